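# Quasi-steady diffusible species.
#
# Molecular timescales (minutes) are short against cellular ones (days),
# so each species J solves the elliptic problem  D_J lap(J) + s_J = 0 with
# zero-flux boundaries.  Every source is of the form  s_J = prod - loss * J
# with prod, loss >= 0 fields; the oxygen loss depends on oxygen itself
# through a Michaelis factor and is solved by damped Picard iteration.
# Solve order: oxygen first, then VEGF and CSF-1 (their production is the
# biphasic hypoxia response of oxygen), then CXCL12, EGF, TGF-beta and the
# drug, none of which sees another chemical except through oxygen.

# linear source decomposition for one species at fixed phases (and fixed
# oxygen where needed); returns list(prod, loss)
species_linear_source <- function(species, phases, params, therapy,
                                  c_field = NULL, t = 0) {
  p <- params
  switch(species,
    g = list(prod = p$k_p_g * (phases$h + phases$c + phases$M2) *
               c_field / (p$c_a + c_field)^2,
             loss = p$k_d_g + p$k_assoc_g * phases$v),
    a = list(prod = p$k_p_a * phases$c * c_field / (p$c_a + c_field)^2,
             loss = p$k_d_a + p$k_assoc_a * phases$M1),
    b = list(prod = p$k_p_b * phases$v,
             loss = p$k_d_b + p$k_assoc_b * phases$M2),
    l = list(prod = p$k_p_l * phases$M2,
             loss = p$k_d_l + p$k_assoc_l * phases$c),
    f = list(prod = p$k_p_f * phases$c,
             loss = p$k_d_f + p$k_assoc_f * phases$M1),
    d = list(prod = therapy$k_rep_d * phases$v *
               drug_vascular_concentration(t, therapy),
             loss = therapy$k_rep_d * phases$v +
               therapy$k_assoc_d * (phases$M1 + phases$M1p) +
               therapy$k_d_d),
    stop("unknown linear species: ", species))
}

#' Net source terms for the diffusible species
#'
#' Pointwise evaluation of each species' production minus consumption at a
#' given state: oxygen supply from the vasculature minus sustenance and
#' mitosis consumption; the biphasic hypoxia-amplified production of VEGF
#' and CSF-1 (`c / (c_a + c)^2`); vascular CXCL12 secretion; M2-derived
#' EGF; cancer-derived TGF-beta; and the drug's vascular delivery minus
#' receptor binding and decay.
#'
#' @param phases a `tp_phase_state`.
#' @param chems a `tp_chemical_state` at which to evaluate the sources.
#' @param t time (enters only the vascular drug concentration).
#' @param params a [model_parameters()] object.
#' @param therapy a [therapy_parameters()] object.
#' @return named list of source fields, one per species.
#' @export
chemical_sources <- function(phases, chems, t, params,
                             therapy = therapy_parameters()) {
  p <- params
  s_c <- p$k_rep * phases$v * (p$c_v_ref - chems$c) -
    (p$k_c_h * phases$h + p$k_c_c * phases$c) * chems$c -
    (p$k_cm_h * phases$h + p$k_cm_c * phases$c) * phases$int *
      chems$c / (p$c_p + chems$c)
  out <- list(c = s_c)
  for (sp in c("g", "a", "b", "l", "f", "d")) {
    ls <- species_linear_source(sp, phases, params, therapy,
                                c_field = chems$c, t = t)
    out[[sp]] <- ls$prod - ls$loss * chems[[sp]]
  }
  out
}

#' Vascular drug concentration under pulsed oral dosing
#'
#' Each of the `N_pills` doses (times `t0_pill + (i-1) T_pill`) raises the
#' vascular concentration by `d_max` and is eliminated exponentially at
#' rate `k_el_d`; contributions of past doses superpose.
#'
#' @param t time(s), vectorized.
#' @param schedule a [therapy_parameters()] object (or any list with
#'   `d_max`, `T_pill`, `t0_pill`, `N_pills`, `k_el_d`).
#' @return nonnegative concentration(s), bounded by
#'   `d_max / (1 - exp(-k_el_d * T_pill))`.
#' @examples
#' th <- therapy_parameters(TRUE)
#' drug_vascular_concentration(99, th)     # 0 before the first dose
#' drug_vascular_concentration(100, th)    # d_max
#' @export
drug_vascular_concentration <- function(t, schedule) {
  if (schedule$N_pills == 0) return(0 * t)
  t_pill <- schedule$t0_pill + (seq_len(schedule$N_pills) - 1) * schedule$T_pill
  out <- 0 * t
  for (tp in t_pill) {
    dt <- t - tp
    out <- out + ifelse(dt >= 0, schedule$d_max * exp(-schedule$k_el_d * dt), 0)
  }
  out
}

# cache of per-species Laplacian operators for a domain.  Radial domains
# store the tridiagonal coefficients (solved by the Thomas algorithm);
# 2D domains store sparse matrices.
chem_operators <- function(domain, params, therapy) {
  D <- c(c = params$D_c, g = params$D_g, a = params$D_a, b = params$D_b,
         l = params$D_l, f = params$D_f, d = therapy$D_d)
  if (domain$mode == "radial_1d") {
    n <- domain$n
    # conductances through interior faces, divided by cell volumes
    w <- domain$area[2:n] / domain$dr
    lo <- c(0, w / domain$vol[2:n])          # coupling of cell k to k-1
    up <- c(w / domain$vol[1:(n - 1)], 0)    # coupling of cell k to k+1
    ops <- lapply(D, function(Dj)
      list(tridiag = TRUE, lo = Dj * lo, up = Dj * up,
           dg = -(Dj * lo + Dj * up)))
  } else {
    lap1 <- laplacian_operator(domain, 1)
    ops <- lapply(D, function(Dj) Dj * lap1)
  }
  ops
}

# Thomas algorithm for a tridiagonal system; dg/lo/up are the diagonal,
# sub- and super-diagonal coefficient vectors (lo[1] = up[n] = 0)
thomas_solve <- function(lo, dg, up, rhs) {
  n <- length(dg)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- up[1] / dg[1]
  dp[1] <- rhs[1] / dg[1]
  for (k in 2:n) {
    m <- dg[k] - lo[k] * cp[k - 1]
    cp[k] <- up[k] / m
    dp[k] <- (rhs[k] - lo[k] * dp[k - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (k in (n - 1):1) x[k] <- dp[k] - cp[k] * x[k + 1]
  x
}

# apply a cached operator to a field
op_apply <- function(Lop, x) {
  if (is.list(Lop)) {
    n <- length(x)
    Lop$dg * x + Lop$lo * c(0, x[-n]) + Lop$up * c(x[-1], 0)
  } else as.numeric(Lop %*% x)
}

# one linear elliptic solve: (D lap - diag(loss)) J = -prod
solve_linear_species <- function(Lop, loss, prod, n) {
  if (is.list(Lop)) {
    thomas_solve(Lop$lo, Lop$dg - loss, Lop$up, -prod)
  } else {
    A <- Lop - Matrix::Diagonal(n, loss)
    as.numeric(Matrix::solve(A, -prod))
  }
}

#' Generic linear reaction--diffusion solve
#'
#' Solves `D lap(J) + prod - loss * J = 0` with zero-flux boundaries.
#' This is the elementary solve behind every linear quasi-steady species;
#' exposed for manufactured-solution convergence studies.
#'
#' @param domain a `tp_domain`.
#' @param D scalar diffusivity.
#' @param loss nonnegative loss-rate field (must be positive somewhere for
#'   a unique solution).
#' @param prod production field.
#' @return the solved cell field.
#' @export
solve_reaction_diffusion <- function(domain, D, loss, prod) {
  if (length(loss) == 1) loss <- rep(loss, domain$n)
  if (length(prod) == 1) prod <- rep(prod, domain$n)
  solve_linear_species(laplacian_operator(domain, D), loss, prod, domain$n)
}

#' Solve one species' quasi-steady field
#'
#' Solves `D_J lap(J) + s_J = 0` with zero-flux boundaries on the given
#' domain.  Oxygen (whose mitotic consumption saturates in oxygen itself)
#' is solved by damped Picard iteration on the Michaelis factor,
#' warm-started from `guess`; all other species are linear in the unknown
#' once the phases (and oxygen) are fixed and take one sparse solve.
#'
#' @param domain a `tp_domain`.
#' @param species one of `"c", "g", "a", "b", "l", "f", "d"`.
#' @param phases a `tp_phase_state`.
#' @param params,therapy parameter objects.
#' @param t time (drug schedule only).
#' @param c_field the oxygen field (required for `"g"` and `"a"`).
#' @param guess optional warm start (oxygen only).
#' @param ops optional operator cache from internal reuse.
#' @param tol residual tolerance on the discrete equation (default 1e-10).
#' @return the solved cell field.
#' @export
solve_quasi_steady <- function(domain, species, phases, params,
                               therapy = therapy_parameters(), t = 0,
                               c_field = NULL, guess = NULL, ops = NULL,
                               tol = 1e-10) {
  if (is.null(ops)) ops <- chem_operators(domain, params, therapy)
  n <- domain$n
  p <- params
  if (species == "c") {
    cc <- guess %||% rep(p$c_p, n)
    base_loss <- p$k_rep * phases$v + p$k_c_h * phases$h + p$k_c_c * phases$c
    mito <- p$k_cm_h * phases$h + p$k_cm_c * phases$c
    prod <- p$k_rep * phases$v * p$c_v_ref
    for (it in 1:100) {
      loss <- base_loss + mito * phases$int / (p$c_p + cc)
      cn <- solve_linear_species(ops[["c"]], loss, prod, n)
      cn <- pmax(cn, 0)
      delta <- max(abs(cn - cc))
      cc <- cn
      if (delta < 1e-13) break
    }
    res <- max(abs(op_apply(ops[["c"]], cc) +
                     prod - base_loss * cc -
                     mito * phases$int * cc / (p$c_p + cc)))
    if (res > tol * max(1, max(abs(cc))))
      stop("oxygen quasi-steady solve did not converge: residual ", res)
    return(cc)
  }
  if (species %in% c("g", "a") && is.null(c_field))
    stop("species ", species, " needs the oxygen field")
  ls <- species_linear_source(species, phases, params, therapy,
                              c_field = c_field, t = t)
  J <- solve_linear_species(ops[[species]], ls$loss, ls$prod, n)
  pmax(J, 0)
}

#' Solve all quasi-steady species at one instant
#'
#' @inheritParams solve_quasi_steady
#' @param prev optional previous `tp_chemical_state` used to warm-start
#'   the oxygen iteration.
#' @return a `tp_chemical_state`.  The drug field is solved only when
#'   `therapy$enabled`; otherwise it is identically zero.
#' @export
solve_all_chemicals <- function(domain, phases, params,
                                therapy = therapy_parameters(), t = 0,
                                prev = NULL, ops = NULL) {
  if (is.null(ops)) ops <- chem_operators(domain, params, therapy)
  cc <- solve_quasi_steady(domain, "c", phases, params, therapy, t,
                           guess = prev$c, ops = ops)
  out <- list(c = cc)
  for (sp in c("g", "a", "b", "l", "f"))
    out[[sp]] <- solve_quasi_steady(domain, sp, phases, params, therapy, t,
                                    c_field = cc, ops = ops)
  out$d <- if (therapy$enabled) {
    solve_quasi_steady(domain, "d", phases, params, therapy, t, ops = ops)
  } else rep(0, domain$n)
  structure(out, class = "tp_chemical_state")
}
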