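# Pointwise reaction terms: phase production/death, the smoothed Heaviside
# occlusion switch, the cell-density pressure closure, and the cell pressure.
#
# All functions are pure and vectorized over cells.  The drug-bound
# macrophage compartment (M1p) is carried everywhere; with the drug field
# identically zero every therapy term vanishes exactly, so the base model
# is the bit-for-bit special case of the extended one.

#' Smoothed Heaviside switch
#'
#' `H(y, h) = (1 + tanh(y / h)) / 2`: a smooth, strictly increasing
#' approximation of the unit step used for vascular occlusion onset.
#'
#' @param y argument (vectorized).
#' @param h_smooth smoothing width (> 0; the switch is sharp for small `h`).
#' @return values in (0, 1).
#' @examples
#' smooth_heaviside(0, 0.2)      # 0.5
#' smooth_heaviside(-0.3, 0.2)   # ~0.0474
#' @export
smooth_heaviside <- function(y, h_smooth) {
  if (!(h_smooth > 0)) stop("h_smooth must be positive")
  (1 + tanh(y / h_smooth)) / 2
}

#' Phase state constructor
#'
#' Bundles the seven volumetric phase concentration fields.  All fields
#' must be nonnegative and finite; omitted fields default to zero.
#'
#' @param .domain a `tp_domain` (dotted name: the single-letter field
#'   names would otherwise partially match it).
#' @param ... named fields among `h, c, v, M1, M1p, M2, int` (scalars fill).
#' @return an object of class `tp_phase_state`: named list of cell fields.
#' @export
phase_state <- function(.domain, ...) {
  given <- list(...)
  unknown <- setdiff(names(given), tp_phases)
  if (length(unknown) > 0)
    stop("unknown phase(s): ", paste(unknown, collapse = ", "))
  st <- stats::setNames(vector("list", 7L), tp_phases)
  for (ph in tp_phases) {
    v <- given[[ph]] %||% 0
    if (length(v) == 1) v <- rep(as.numeric(v), .domain$n)
    if (length(v) != .domain$n) stop("phase ", ph, " has wrong length")
    if (any(!is.finite(v)) || any(v < 0))
      stop("phase ", ph, " must be finite and nonnegative")
    st[[ph]] <- as.numeric(v)
  }
  structure(st, class = "tp_phase_state")
}

#' Chemical state constructor
#'
#' Bundles the seven diffusible concentration fields (oxygen `c`, VEGF `g`,
#' CSF-1 `a`, CXCL12 `b`, EGF `l`, TGF-beta `f`, drug `d`).
#'
#' @param .domain a `tp_domain` (dotted name: the single-letter species
#'   names would otherwise partially match it).
#' @param ... named fields among the species names (scalars fill).
#' @return an object of class `tp_chemical_state`.
#' @export
chemical_state <- function(.domain, ...) {
  given <- list(...)
  unknown <- setdiff(names(given), tp_chemicals)
  if (length(unknown) > 0)
    stop("unknown chemical(s): ", paste(unknown, collapse = ", "))
  st <- stats::setNames(vector("list", 7L), tp_chemicals)
  for (sp in tp_chemicals) {
    v <- given[[sp]] %||% 0
    if (length(v) == 1) v <- rep(as.numeric(v), .domain$n)
    if (length(v) != .domain$n) stop("chemical ", sp, " has wrong length")
    if (any(!is.finite(v)) || any(v < 0))
      stop("chemical ", sp, " must be finite and nonnegative")
    st[[sp]] <- as.numeric(v)
  }
  structure(st, class = "tp_chemical_state")
}

# total cell density entering the pressure closure: healthy + cancer +
# all macrophage compartments (drug-bound included; zero when therapy off)
closure_density <- function(phases) {
  phases$h + phases$c + phases$M1 + phases$M1p + phases$M2
}

#' Cell-density pressure closure
#'
#' Pressure buildup when the local cell density `theta = theta_h + theta_c
#' + theta_M1 + theta_M1p + theta_M2` exceeds the natural tissue density
#' `theta*`: `Sigma = Lambda (theta - theta*) / D` with `D` the sum of
#' squared deviations `(theta_i - theta)^2` over the six base phases
#' (healthy, cancer, vessels, M1, M2, interstitium), and `Sigma = 0` below
#' `theta*`.  A small floor (`eps_den`, default `1e-8`) guards the
#' denominator against the degenerate all-deviations-zero case; results
#' are insensitive to its exact value.
#'
#' @param phases a `tp_phase_state`.
#' @param params a [model_parameters()] object (`Lambda`, `theta_star`).
#' @param eps_den denominator floor.
#' @return cell field of `Sigma` (continuous at `theta = theta*`).
#' @export
sigma_closure <- function(phases, params, eps_den = 1e-8) {
  th <- closure_density(phases)
  dev2 <- (phases$h - th)^2 + (phases$c - th)^2 + (phases$v - th)^2 +
    (phases$M1 - th)^2 + (phases$M2 - th)^2 + (phases$int - th)^2
  out <- params$Lambda * pmax(th - params$theta_star, 0) / (dev2 + eps_den)
  out
}

#' Total pressure exerted by the cellular phases
#'
#' Concentration-weighted mean of the cellular pressures over the total
#' phase concentration: `p_cell = (theta_h p_h + theta_c p_c + theta_M1
#' p_M1 + theta_M1p p_M1p + theta_M2 p_M2) / sum_i theta_i`, the pressure
#' felt by immature vessels (occlusion above `p_crit`).
#'
#' @param phases a `tp_phase_state`.
#' @param p_h,p_c,p_M1,p_M1p,p_M2 cellular pressure fields.
#' @return cell field of `p_cell`.
#' @export
cell_pressure <- function(phases, p_h, p_c, p_M1, p_M1p = 0, p_M2) {
  tot <- phases$h + phases$c + phases$v + phases$M1 + phases$M1p +
    phases$M2 + phases$int
  if (any(tot <= 1e-10))
    stop("total phase concentration vanishes; cell pressure undefined")
  (phases$h * p_h + phases$c * p_c + phases$M1 * p_M1 +
     phases$M1p * p_M1p + phases$M2 * p_M2) / tot
}

#' Net production rates for all phases
#'
#' Evaluates the reaction terms of the mass balances pointwise:
#' * healthy cells: oxygen- and fluid-limited proliferation minus
#'   oxygen-dependent death;
#' * cancer cells: proliferation boosted by M2 presence, death, and
#'   killing by (unbound plus drug-bound) M1 macrophages;
#' * vessels: VEGF-driven angiogenesis minus pressure-triggered occlusion;
#' * M1: CSF-1-saturated extravasation from the vasculature minus death,
#'   alternative activation to M2, and drug binding (conversion to M1p);
#' * M1p: drug conversion source minus death;
#' * M2: alternative activation source minus death;
#' * interstitial fluid: balances every other contribution so that the
#'   only net mass source of the mixture is M1 extravasation.
#'
#' @param phases a `tp_phase_state` (nonnegative fields; callers clip).
#' @param chems a `tp_chemical_state`.
#' @param p_cell cell-pressure field (scalar 0 allowed for uniform states).
#' @param params a [model_parameters()] object.
#' @param therapy a [therapy_parameters()] object; drug terms use its
#'   constants and vanish identically when the drug field is zero.
#' @return an object of class `tp_phase_rates`: named list `q_h, q_c, q_v,
#'   q_M1, q_M1p, q_M2, q_int` plus `qbar_M1` (the M1 sink-only part) and
#'   `extravasation` (the mixture's only external mass source).
#' @export
production_terms <- function(phases, chems, p_cell, params,
                             therapy = therapy_parameters()) {
  p <- params
  for (ph in tp_phases) if (any(phases[[ph]] < 0))
    stop("negative phase concentration in ", ph,
         "; clip before evaluating production terms")
  ox_prolif <- chems$c / (p$c_p + chems$c)
  ox_death  <- (p$c_c1 + chems$c) / (p$c_c2 + chems$c)

  q_h <- p$k_m_h * phases$h * phases$int * ox_prolif -
    p$k_d_h * phases$h * ox_death

  m1_tot <- phases$M1 + phases$M1p
  q_c <- (p$k_m_c + p$k_c_M2 * phases$M2 / (p$theta_M + phases$M2)) *
    phases$c * phases$int * ox_prolif -
    p$k_d_c * phases$c * ox_death -
    p$k_c_M1 * phases$c * m1_tot / (p$theta_M + m1_tot)

  q_v <- p$k_ang * phases$v * chems$g * phases$int / (p$eps + phases$int) -
    p$k_occ * phases$v * smooth_heaviside(p_cell - p$p_crit, p$h_smooth)

  extrav <- p$k_ext_M1 * phases$v * chems$a / (p$a_p + chems$a)
  aa <- p$k_aa * phases$M1 * chems$f / (p$f_p + chems$f)
  conv <- therapy$k_assoc_M1 * phases$M1 * chems$d / (therapy$d_p + chems$d)

  qbar_M1 <- -p$k_d_M1 * phases$M1 - aa
  q_M1 <- extrav + qbar_M1 - conv
  q_M1p <- conv - therapy$k_d_M1p * phases$M1p
  q_M2 <- aa - p$k_d_M2 * phases$M2
  # interstitium balances everything except extravasation; conversion
  # cancels between q_M1 and q_M1p, and M1p death feeds the fluid
  q_int <- -(q_h + q_c + q_v + q_M2 + qbar_M1) +
    therapy$k_d_M1p * phases$M1p

  structure(list(q_h = q_h, q_c = q_c, q_v = q_v, q_M1 = q_M1,
                 q_M1p = q_M1p, q_M2 = q_M2, q_int = q_int,
                 qbar_M1 = qbar_M1, extravasation = extrav),
            class = "tp_phase_rates")
}
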