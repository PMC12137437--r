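# Explicit conservative transport of the volumetric phases.
#
# Each phase moves with its own flow velocity plus a chemotactic drift
# chi_J grad(J) along its designated chemokine (cancer <- EGF, vessels <-
# VEGF, M1 and drug-bound M1 <- CSF-1, M2 <- CXCL12; healthy cells and
# interstitial fluid are not chemotactic).  Fluxes are first-order
# upwinded, which preserves positivity under the CFL bound.  On boundary
# faces, inflow (face velocity pointing into the domain) carries the
# far-field homeostatic concentrations; outflow carries the upwind
# interior value.

tp_chemo_pairs <- list(c = "l", v = "g", M1 = "a", M1p = "a", M2 = "b")

chemo_strength <- function(params, ph) {
  switch(ph, c = params$chi_l, v = params$chi_g, M1 = params$chi_a,
         M1p = params$chi_a, M2 = params$chi_b, 0)
}

# total face velocity (advective + chemotactic) per phase.
# 1D: list of length-(n+1) face vectors.  2D: list of lists (x, y, bx, by).
face_velocities <- function(domain, flow, chems, params) {
  out <- stats::setNames(vector("list", 7L), tp_phases)
  for (ph in tp_phases) {
    chi <- chemo_strength(params, ph)
    J <- tp_chemo_pairs[[ph]]
    if (domain$mode == "radial_1d") {
      w <- flow$u[[ph]]
      if (chi > 0 && !is.null(J)) w <- w + chi * gradient(domain, chems[[J]])
      out[[ph]] <- w
    } else {
      w <- flow$u[[ph]]
      if (chi > 0 && !is.null(J)) {
        gJ <- gradient(domain, chems[[J]])
        w <- list(x = w$x + chi * gJ$x, y = w$y + chi * gJ$y,
                  bx = w$bx, by = w$by)     # zero-flux chemokine boundary
      }
      out[[ph]] <- w
    }
  }
  out
}

#' Stable time step for the explicit transport update
#'
#' `dt = cfl * min(cell width / |face speed|)` over all faces and phases
#' (advective plus chemotactic speeds), capped by `dt_max` and by the time
#' remaining to the next event (dose time, output time, end time), so that
#' events land exactly on step boundaries.  In 2D the bound is per face,
#' uses the smaller adjacent (possibly boundary-clipped) cell volume, and
#' carries a factor two for simultaneous drainage in both directions.
#'
#' @param domain a `tp_domain`.
#' @param flow a `tp_flow` from [solve_flow()].
#' @param chems a `tp_chemical_state`.
#' @param params a [model_parameters()] object.
#' @param cfl Courant number in (0, 1].
#' @param dt_max step cap used when all speeds vanish.
#' @param t current time.
#' @param events sorted vector of future event times (may be empty).
#' @return the time step.
#' @export
compute_dt <- function(domain, flow, chems, params, cfl = 0.4,
                       dt_max = 0.1, t = 0, events = numeric(0)) {
  w <- face_velocities(domain, flow, chems, params)
  dt <- dt_max
  if (domain$mode == "radial_1d") {
    wmax <- 0
    for (ph in tp_phases) wmax <- max(wmax, abs(w[[ph]]))
    if (wmax > 0) dt <- min(dt, cfl * domain$dr / wmax)
  } else {
    # per-face bound honoring clipped boundary-cell volumes: a cell may
    # drain through faces in both directions at once, hence the factor 2
    dx <- domain$dx
    vminx <- pmin(domain$vol[domain$fx$L], domain$vol[domain$fx$R])
    vminy <- pmin(domain$vol[domain$fy$L], domain$vol[domain$fy$R])
    vbx <- domain$vol[domain$fx$b_owner]
    vby <- domain$vol[domain$fy$b_owner]
    for (ph in tp_phases) {
      sp <- abs(c(w[[ph]]$x, w[[ph]]$y, w[[ph]]$bx, w[[ph]]$by))
      vv <- c(vminx, vminy, vbx, vby)
      act <- sp > 0
      if (any(act))
        dt <- min(dt, cfl * min(vv[act] / (2 * dx * sp[act])))
    }
  }
  events <- events[events > t + 1e-12]
  if (length(events) > 0) dt <- min(dt, min(events) - t)
  dt
}

#' Advance the phase mass balances by one explicit step
#'
#' Conservative first-order upwind update of every phase with its
#' advective + chemotactic face velocity and reaction rate.  Values driven
#' into `(-1e-10, 0)` by round-off are floored to zero; anything below
#' `-1e-10` aborts (CFL violation or upstream defect).
#'
#' @param domain a `tp_domain`.
#' @param phases current `tp_phase_state`.
#' @param flow `tp_flow` at the current instant.
#' @param chems `tp_chemical_state` at the current instant.
#' @param rates `tp_phase_rates` from [production_terms()].
#' @param dt time step (caller enforces the CFL bound via [compute_dt()]).
#' @param params a [model_parameters()] object.
#' @param theta_inf named far-field concentrations imposed on inflow
#'   boundary faces (the homeostatic initial state).
#' @return an object of class `tp_step`: `phases` (updated state), `dt`,
#'   `cfl` (realized Courant number), `mass_budget` (list: `delta_mass`,
#'   `source_integral`, `boundary_outflux`, `closure_error` -- the
#'   discrete identity `delta = dt (source - outflux)` holds to round-off),
#'   and `range` (min/max per phase).
#' @export
advance_phases <- function(domain, phases, flow, chems, rates, dt, params,
                           theta_inf) {
  w <- face_velocities(domain, flow, chems, params)
  h <- if (domain$mode == "radial_1d") domain$dr else domain$dx
  qof <- list(h = rates$q_h, c = rates$q_c, v = rates$q_v, M1 = rates$q_M1,
              M1p = rates$q_M1p, M2 = rates$q_M2, int = rates$q_int)
  new <- phases
  mass_old <- 0; mass_new <- 0; bflux <- 0; wmax <- 0
  for (ph in tp_phases) {
    th <- phases[[ph]]
    if (domain$mode == "radial_1d") {
      n <- domain$n
      wf <- w[[ph]]
      up <- c(0, ifelse(wf[2:n] >= 0, th[1:(n - 1)], th[2:n]), 0)
      # boundary face: outflow takes the interior value, inflow the
      # far-field homeostatic value
      up[n + 1] <- if (wf[n + 1] >= 0) th[n] else theta_inf[[ph]]
      flux <- up * wf
      div <- divergence(domain, flux)
      bflux <- bflux + domain$area[n + 1] * flux[n + 1]
      wmax <- max(wmax, abs(wf))
    } else {
      wf <- w[[ph]]
      upx <- ifelse(wf$x >= 0, th[domain$fx$L], th[domain$fx$R])
      upy <- ifelse(wf$y >= 0, th[domain$fy$L], th[domain$fy$R])
      upbx <- ifelse(wf$bx >= 0, th[domain$fx$b_owner], theta_inf[[ph]])
      upby <- ifelse(wf$by >= 0, th[domain$fy$b_owner], theta_inf[[ph]])
      flux <- list(x = upx * wf$x, y = upy * wf$y,
                   bx = upbx * wf$bx, by = upby * wf$by)
      div <- divergence(domain, flux)
      bflux <- bflux + domain$dx * (sum(flux$bx) + sum(flux$by))
      wmax <- max(wmax, abs(wf$x), abs(wf$y), abs(wf$bx), abs(wf$by))
    }
    thn <- th + dt * (qof[[ph]] - div)
    if (any(thn < -1e-10))
      stop("phase ", ph, " went negative (min ", min(thn),
           "); reduce the CFL number or the step size")
    thn[thn < 0] <- 0
    new[[ph]] <- thn
    mass_old <- mass_old + volume_integral(domain, th)
    mass_new <- mass_new + volume_integral(domain, thn)
  }
  src <- volume_integral(domain, rates$extravasation)
  # flooring of round-off negatives perturbs the identity at ~1e-10 * vol
  closure <- (mass_new - mass_old) - dt * (src - bflux)
  structure(list(
    phases = new, dt = dt, cfl = wmax * dt / h,
    mass_budget = list(delta_mass = mass_new - mass_old,
                       source_integral = dt * src,
                       boundary_outflux = dt * bflux,
                       closure_error = closure),
    range = sapply(new, range)), class = "tp_step")
}
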