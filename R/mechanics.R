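# Multiphase creeping flow: per-phase momentum balances with viscous
# stress and inter-phase drag, coupled by a mixture continuity equation
# that determines the interstitial pressure.
#
# For each phase i:  div(theta_i sigma_i) + p_i grad(theta_i)
#                    + sum_j d_ij theta_i theta_j (u_j - u_i) = 0,
# with sigma_i = -p_i I + mu_i (grad u + grad u^T) - (2/3) mu_i div(u) I.
# The pressure terms combine to -theta_i grad p_i.  Phase pressures are
# p_v = 0, p_int, and p_cellular = p_int + Sigma(theta).  Boundary
# conditions: stress-free (sigma_i . n = 0) for all phases except the
# interstitial fluid, which satisfies u_int = 0 on the outer boundary;
# symmetry (u = 0) at the disk center.
#
# Mixture continuity: sum_i div(theta_i u_i) = rhs, where rhs collects the
# chemotactic flux divergences (the reaction terms cancel against the
# extravasation source by construction of q_int).  The discrete system is
# a sparse saddle-point problem in all seven face-velocity fields plus the
# cell-centered interstitial pressure, solved by direct sparse LU.
#
# Phases locally absent are regularized by a concentration floor inside
# the viscous/drag/pressure coefficients; their velocities are
# diagnostically meaningless there but carry no mass (continuity uses the
# unfloored concentrations).

tp_theta_floor <- 1e-8

#' Solve the multiphase flow problem (1D radial)
#'
#' Returns all seven phase velocities (radial, on faces) and the
#' interstitial pressure (on cells) satisfying the discretized momentum
#' and mixture-continuity equations.  Deterministic; direct sparse solve.
#'
#' @param domain a radial `tp_domain`.
#' @param phases a `tp_phase_state`.
#' @param params a [model_parameters()] object.
#' @param sigma pressure-closure field from [sigma_closure()]; computed
#'   from `phases` when `NULL`.
#' @param continuity_rhs cell field for the mixture continuity right-hand
#'   side (minus the chemotactic flux divergence in a model run; zero
#'   default).
#' @param body_force optional named list of per-phase face forces (length
#'   `n`, faces at `r > 0`), used by manufactured-solution tests.
#' @param bc_stress optional named list of boundary normal-stress values
#'   per phase (default 0, the stress-free condition).
#' @return an object of class `tp_flow`: list with `u` (named list of
#'   face-velocity vectors of length `n + 1`, first entry the center face
#'   where symmetry imposes `u = 0`), `p_int` (cells), `sigma`, `p_cell`,
#'   and `residual` (max-norm of the assembled linear system's residual).
#' @export
solve_flow <- function(domain, phases, params, sigma = NULL,
                       continuity_rhs = NULL, body_force = NULL,
                       bc_stress = NULL) {
  if (domain$mode == "cartesian_2d")
    return(solve_flow_2d(domain, phases, params, sigma, continuity_rhs))
  n <- domain$n
  dr <- domain$dr
  rc <- domain$r_cell
  rf <- domain$r_face            # length n + 1, rf[1] = 0
  if (is.null(sigma)) sigma <- sigma_closure(phases, params)
  if (is.null(continuity_rhs)) continuity_rhs <- rep(0, n)

  mu <- params$mu
  dmat <- params$d_drag
  nun <- 7L * n + n              # unknowns: 7 face-velocity fields + p_int
  # unknown indexing: phase p face k (k = 1..n, face at r = k dr) ->
  # (p-1)*n + k ; pressure cell k -> 7n + k
  uix <- function(p, k) (p - 1L) * n + k
  pix <- function(k) 7L * n + k

  trips <- vector("list", 256L); ntrip <- 0L
  rhs <- numeric(nun)
  add <- function(i, j, x) {
    ntrip <<- ntrip + 1L
    trips[[ntrip]] <<- cbind(i, j, x)
  }

  thf <- lapply(phases, pmax, tp_theta_floor)   # floored, coefficients
  # face averages of floored concentrations (faces k = 1..n; face n uses
  # the boundary cell value)
  favg <- lapply(thf, function(v) c((v[-n] + v[-1]) / 2, v[n]))
  # unfloored face averages for the continuity equation
  favg0 <- lapply(phases[tp_phases], function(v) c((v[-n] + v[-1]) / 2, v[n]))

  has_pint <- stats::setNames(tp_phases != "v", tp_phases)   # p_v = 0
  cellular <- tp_phases %in% tp_cellular

  ki <- seq_len(n - 1)           # interior faces
  for (p in seq_along(tp_phases)) {
    ph <- tp_phases[p]
    th <- thf[[ph]]
    mup <- mu[[ph]]
    row <- uix(p, ki)

    # radial viscous flux difference: (1/(r_f dr)) [ rc_{k+1} th_{k+1}
    #   s_{k+1} - rc_k th_k s_k ],  s_j = mu (4/3 u'_j - (1/3)(u_k+u_{k-1})/rc_j)
    pref <- 1 / (rf[ki + 1] * dr)
    aU <- pref * rc[ki + 1] * th[ki + 1] * mup   # upper-cell weight
    aL <- pref * rc[ki]     * th[ki]     * mup   # lower-cell weight
    c_up <- 4 / (3 * dr)
    # s_{k+1} involves u_{k+1}, u_k ; s_k involves u_k, u_{k-1}
    add(row, uix(p, ki + 1),  aU * (c_up - 1 / (3 * rc[ki + 1])))
    add(row, uix(p, ki),      aU * (-c_up - 1 / (3 * rc[ki + 1])))
    add(row, uix(p, ki),     -aL * (c_up - 1 / (3 * rc[ki])))
    km <- ki[ki >= 2]
    add(uix(p, km), uix(p, km - 1),
        -pref[km] * rc[km] * th[km] * mup * (-c_up - 1 / (3 * rc[km])))

    # hoop term: - th_f mu (4/3 u_k / r_f - 2/3 u'_f) / r_f,
    # u'_f = (u_{k+1} - u_{k-1}) / (2 dr)   (u_0 = 0 at the center face)
    thfc <- favg[[ph]][ki]
    add(row, uix(p, ki), -thfc * mup * 4 / (3 * rf[ki + 1]^2))
    add(row, uix(p, ki + 1),  thfc * mup / (3 * dr * rf[ki + 1]))
    add(uix(p, km), uix(p, km - 1), -favg[[ph]][km] * mup / (3 * dr * rf[km + 1]))

    # pressure gradient: -th_f (p_{i,k+1} - p_{i,k}) / dr
    if (has_pint[[ph]]) {
      add(row, pix(ki + 1), -thfc / dr)
      add(row, pix(ki),      thfc / dr)
    }
    if (cellular[p])   # known Sigma part of the cellular pressure -> RHS
      rhs[row] <- rhs[row] + thfc * (sigma[ki + 1] - sigma[ki]) / dr

    # drag against every other phase
    for (q in seq_along(tp_phases)) {
      if (q == p) next
      dpq <- dmat[p, q]
      if (dpq == 0) next
      w <- dpq * thfc * favg[[tp_phases[q]]][ki]
      add(row, uix(q, ki),  w)
      add(row, uix(p, ki), -w)
    }

    if (!is.null(body_force) && !is.null(body_force[[ph]]))
      rhs[row] <- rhs[row] - body_force[[ph]][ki]

    # boundary row (face n at r = R)
    brow <- uix(p, n)
    if (ph == "int") {
      add(brow, uix(p, n), 1)    # u_int(R) = 0
    } else {
      # sigma_rr(R) = 0:  mu (4/3 u'(R) - 2/3 u(R)/R) - p_i(R) = 0, with
      # second-order one-sided u'(R) and linearly extrapolated p_i(R)
      add(brow, uix(p, n),
          mup * (4 / 3) * 3 / (2 * dr) - mup * 2 / (3 * domain$R))
      add(brow, uix(p, n - 1), -mup * (4 / 3) * 4 / (2 * dr))
      add(brow, uix(p, n - 2),  mup * (4 / 3) * 1 / (2 * dr))
      sig_R <- 1.5 * sigma[n] - 0.5 * sigma[n - 1]
      if (has_pint[[ph]]) {
        add(brow, pix(n), -1.5)
        add(brow, pix(n - 1), 0.5)
      }
      if (cellular[p]) rhs[brow] <- rhs[brow] + sig_R
      if (!is.null(bc_stress) && !is.null(bc_stress[[ph]]))
        rhs[brow] <- rhs[brow] + bc_stress[[ph]]
    }
  }

  # mixture continuity per cell (unfloored concentrations carry the mass)
  A <- domain$area                 # face areas, length n + 1
  V <- domain$vol
  for (p in seq_along(tp_phases)) {
    ph <- tp_phases[p]
    kf <- seq_len(n)               # upper face of cell k is face k
    add(pix(kf), uix(p, kf), A[kf + 1] * favg0[[ph]][kf] / V[kf])
    k2 <- 2:n                      # lower face of cell k (k >= 2)
    add(pix(k2), uix(p, k2 - 1), -A[k2] * favg0[[ph]][k2 - 1] / V[k2])
  }
  rhs[pix(seq_len(n))] <- continuity_rhs

  tr <- do.call(rbind, trips[seq_len(ntrip)])
  keep <- tr[, 3] != 0
  M <- Matrix::sparseMatrix(i = tr[keep, 1], j = tr[keep, 2],
                            x = tr[keep, 3], dims = c(nun, nun))
  sol <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                  error = function(e)
                    stop("flow solve failed (singular system): ",
                         conditionMessage(e)))
  resid <- max(abs(M %*% sol - rhs))

  u <- stats::setNames(vector("list", 7L), tp_phases)
  for (p in seq_along(tp_phases))
    u[[tp_phases[p]]] <- c(0, sol[uix(p, seq_len(n))])
  p_int <- sol[pix(seq_len(n))]

  pc <- cell_pressure(phases,
                      p_h = p_int + sigma, p_c = p_int + sigma,
                      p_M1 = p_int + sigma, p_M1p = p_int + sigma,
                      p_M2 = p_int + sigma)
  structure(list(u = u, p_int = p_int, sigma = sigma, p_cell = pc,
                 residual = resid), class = "tp_flow")
}
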