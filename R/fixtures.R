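# Synthetic test inputs: randomized valid states and manufactured
# solutions with closed-form oracles.  This is the only place in the
# package where a random number generator appears; the simulation core is
# deterministic.

# smooth positive random field from a few low-order cosine modes
smooth_random_field <- function(domain, lo, hi, nmodes = 3L) {
  x <- if (domain$mode == "radial_1d") domain$r_cell / domain$R else
    (domain$x + domain$y) / (2 * domain$R)
  y <- if (domain$mode == "radial_1d") rep(0, domain$n) else
    (domain$x - domain$y) / (2 * domain$R)
  f <- rep(0, domain$n)
  for (k in seq_len(nmodes))
    f <- f + stats::runif(1, -1, 1) * cos(k * pi * x) *
      cos((k - 1) * pi * y + stats::runif(1, 0, pi))
  f <- (f - min(f)) / max(max(f) - min(f), 1e-12)    # map to [0, 1]
  lo + (hi - lo) * f
}

#' Random valid phase/chemical state
#'
#' Smooth positive fields with total phase concentration near one,
#' reproducible per seed.  Intended for property-style tests.
#'
#' @param domain a `tp_domain`.
#' @param seed integer RNG seed.
#' @param with_m1p include a nonzero drug-bound compartment.
#' @return list with `phases` (`tp_phase_state`) and `chems`
#'   (`tp_chemical_state`).
#' @export
random_valid_state <- function(domain, seed, with_m1p = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  h   <- smooth_random_field(domain, 0.30, 0.55)
  cc  <- smooth_random_field(domain, 0.00, 0.25)
  v   <- smooth_random_field(domain, 0.005, 0.03)
  M1  <- smooth_random_field(domain, 0.00, 0.05)
  M1p <- if (with_m1p) smooth_random_field(domain, 0, 0.03) else 0
  M2  <- smooth_random_field(domain, 0.00, 0.05)
  int <- pmax(1 - h - cc - v - M1 - M2 - M1p, 0.05)
  phases <- phase_state(domain, h = h, c = cc, v = v, M1 = M1, M1p = M1p,
                        M2 = M2, int = int)
  chems <- chemical_state(domain,
    c = smooth_random_field(domain, 0.05, 0.6),
    g = smooth_random_field(domain, 0.1, 1.0),
    a = smooth_random_field(domain, 0.0, 0.5),
    b = smooth_random_field(domain, 0.0, 4.0),
    l = smooth_random_field(domain, 0.0, 0.5),
    f = smooth_random_field(domain, 0.0, 0.1),
    d = if (with_m1p) smooth_random_field(domain, 0, 0.5) else 0)
  list(phases = phases, chems = chems)
}

#' Manufactured cases with closed-form oracles
#'
#' Returns the inputs and the analytic solution for one of the registered
#' verification problems:
#' \describe{
#'   \item{diffusion_cosine}{`J*(r) = 2 + cos(pi r / R)` solves the linear
#'     reaction-diffusion problem whose source is built from `J*`; checks
#'     the elliptic solver at design order (radial domains).}
#'   \item{advection_bump}{a Gaussian bump advected radially at constant
#'     speed; the method-of-characteristics solution
#'     `theta(r, t) = theta0(r - u t) (r - u t) / r` is exact.}
#'   \item{drag_balance}{two active phases with negligible viscosity and a
#'     linear body force on one; the drag-dominated velocities are linear
#'     in radius and known in closed form.}
#'   \item{stokes_poly}{one viscous phase with polynomial velocity and
#'     smooth pressure; the momentum/continuity forcing is derived
#'     symbolically, and the solver must recover `(u*, p*)`.}
#' }
#' Every case re-checks its own analytic identity before returning.
#'
#' @param name registry key (see above).
#' @param domain a radial `tp_domain`.
#' @return a list whose components depend on the case (documented fields:
#'   `exact`, plus the inputs needed to run the corresponding solver).
#' @export
manufactured_case <- function(name, domain) {
  if (domain$mode != "radial_1d")
    stop("manufactured cases are defined on radial domains")
  R <- domain$R
  r <- domain$r_cell
  switch(name,
    diffusion_cosine = {
      D <- 0.05
      Jex <- function(r) 2 + cos(pi * r / R)
      lapJ <- function(r) -(pi / R)^2 * cos(pi * r / R) -
        (pi / R) * sin(pi * r / R) / r
      loss <- rep(1, domain$n)
      prod <- loss * Jex(r) - D * lapJ(r)
      # self-check: D lap J* + prod - loss J* == 0 analytically
      stopifnot(max(abs(D * lapJ(r) + prod - loss * Jex(r))) < 1e-12)
      list(name = name, D = D, loss = loss, prod = prod, exact = Jex(r),
           exact_fn = Jex)
    },
    advection_bump = {
      u0 <- 0.5
      r0 <- R / 2
      wdt <- R / 12
      th0 <- function(r) exp(-((r - r0) / wdt)^2)
      exact <- function(r, t) {
        rr <- r - u0 * t
        ifelse(rr > 0, th0(rr) * rr / r, 0)
      }
      list(name = name, u0 = u0, theta0 = th0(r), exact_fn = exact)
    },
    drag_balance = {
      th1 <- 0.35; th2 <- 0.2; dcoef <- 1; F0 <- 0.02
      u1 <- F0 * r * th2 / (dcoef * th1 * (th1 + th2)^2)
      u2 <- -th1 * u1 / th2
      # self-check: momentum balance of the forced phase (viscousless)
      pgrad <- F0 * r / (th1 + th2)
      res <- -th1 * pgrad + F0 * r + dcoef * th1 * th2 * (u2 - u1)
      stopifnot(max(abs(res)) < 1e-12)
      rf <- domain$r_face[-1]
      list(name = name, theta1 = th1, theta2 = th2, F0 = F0,
           body_force_face = F0 * rf,
           exact_u1 = F0 * rf * th2 / (dcoef * th1 * (th1 + th2)^2),
           exact_u2 = -th1 / th2 * F0 * rf * th2 /
             (dcoef * th1 * (th1 + th2)^2))
    },
    stokes_poly = {
      th <- 0.5; mu <- 10
      ue <- quote(r * (1 - (r / R)^2))
      pe <- quote(1 + (r / R)^2)
      du <- D(ue, "r")
      # s = mu (4/3 u' - 2/3 u / r); viscous force =
      #   (1/r) d/dr (theta r s) - theta mu (4/3 u/r - 2/3 u') / r
      s_expr <- substitute(mu * (4 / 3 * DU - 2 / 3 * (UE) / r),
                           list(DU = du, UE = ue))
      rs <- substitute(r * S, list(S = s_expr))
      drs <- D(rs, "r")
      ev <- function(e, rr) eval(e, list(r = rr, R = R, mu = mu))
      visc <- function(rr) th * (ev(drs, rr) / rr -
        mu * (4 / 3 * ev(ue, rr) / rr - 2 / 3 * ev(du, rr)) / rr)
      dp <- D(pe, "r")
      force <- function(rr) th * ev(dp, rr) - visc(rr)   # body force
      rhs_cont <- function(rr) th * (ev(du, rr) + ev(ue, rr) / rr)
      sR <- -ev(pe, R) + ev(s_expr, R)                   # sigma_rr(R)
      list(name = name, theta = th, mu = mu,
           exact_u = function(rr) ev(ue, rr),
           exact_p = function(rr) ev(pe, rr),
           body_force_fn = force, continuity_rhs_fn = rhs_cont,
           bc_stress = sR)
    },
    stop("unknown manufactured case: ", name))
}
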