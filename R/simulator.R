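# Scenario orchestration: equilibrate -> initialize -> split-step time
# loop -> observables.
#
# Each step performs, in order: (1) quasi-steady chemical solves, (2) the
# pressure closure and multiphase flow solve, (3) reaction-rate
# evaluation, (4) an explicit conservative transport update.  Dose times
# from the therapy schedule are always included in the event list (even
# for untreated runs) so that treated and untreated trajectories share
# identical step sequences and can be compared bit for bit.

#' Run one scenario end to end
#'
#' @param scen a [scenario()] object.
#' @param params base [model_parameters()]; scenario overrides and the
#'   macrophage-mode restriction are applied on top.
#' @param verbose 0 (silent), 1 (per-output-event lines), 2 (per-step).
#' @param restart optional snapshot (from [load_snapshot()]) to continue
#'   from instead of the homeostatic initial state.
#' @return an object of class `tp_run`: list with `observables` (one row
#'   per output time), `phases`, `chems`, `flow` (final states), `homeo`,
#'   `domain`, `params` (effective), `t`, and `stats` (step count, maximum
#'   flow residual, realized CFL, cumulative mass-budget closure error,
#'   initial/final total mass with the integrated extravasation source and
#'   boundary outflux, wall time in seconds).
#' @export
run_scenario <- function(scen, params = model_parameters(), verbose = 0,
                         restart = NULL) {
  stopifnot(inherits(scen, "tp_scenario"))
  t_wall <- proc.time()[["elapsed"]]
  eff <- effective_parameters(params, scen)
  therapy <- scen$therapy
  homeo <- solve_homeostasis(eff)
  domain <- make_domain(scen$domain)
  if (length(scen$seeds) > 1 && domain$mode == "radial_1d")
    stop("multi-seed scenarios require a cartesian_2d domain")

  if (is.null(restart)) {
    init <- initial_state(domain, homeo, scen$seeds, eff$theta_star)
    phases <- init$phases
    chems <- init$chems
    t <- 0
  } else {
    phases <- restart$phases
    chems <- restart$chems
    t <- restart$t
  }
  theta_inf <- list(h = eff$theta_star, c = 0, v = homeo$theta_v0,
                    M1 = 0, M1p = 0, M2 = 0, int = homeo$theta_int0)

  ops <- chem_operators(domain, eff, therapy)
  dose_times <- if (therapy$N_pills > 0)
    therapy$t0_pill + (seq_len(therapy$N_pills) - 1) * therapy$T_pill
  else numeric(0)
  out_times <- unique(sort(c(seq(0, scen$t_end, by = scen$output_every),
                             scen$t_end)))
  events <- sort(unique(c(dose_times, out_times)))

  obs <- list()
  nsteps <- 0L
  max_resid <- 0; max_cfl <- 0; closure_acc <- 0
  src_acc <- 0; bflux_acc <- 0
  mass0 <- sum(vapply(tp_phases, function(ph)
    volume_integral(domain, phases[[ph]]), numeric(1)))
  flow <- NULL
  record <- function(t, phases) observable_record(domain, t, phases)
  next_out <- out_times[out_times >= t - 1e-9][1]
  if (abs(t - next_out) < 1e-9) {
    obs[[length(obs) + 1L]] <- record(t, phases)
    next_out <- out_times[out_times > t + 1e-9][1]
  }

  while (t < scen$t_end - 1e-9) {
    chems <- solve_all_chemicals(domain, phases, eff, therapy, t,
                                 prev = chems, ops = ops)
    sigma <- sigma_closure(phases, eff)
    rhs <- -chemotaxis_divergence(domain, phases, chems, eff)
    flow <- solve_flow(domain, phases, eff, sigma, continuity_rhs = rhs)
    rates <- production_terms(phases, chems, flow$p_cell, eff, therapy)
    dt <- compute_dt(domain, flow, chems, eff, cfl = scen$cfl,
                     dt_max = scen$dt_max, t = t, events = events)
    dt <- min(dt, scen$t_end - t)
    step <- advance_phases(domain, phases, flow, chems, rates, dt, eff,
                           theta_inf)
    phases <- step$phases
    t <- t + dt
    nsteps <- nsteps + 1L
    max_resid <- max(max_resid, flow$residual)
    max_cfl <- max(max_cfl, step$cfl)
    closure_acc <- closure_acc + abs(step$mass_budget$closure_error)
    src_acc <- src_acc + step$mass_budget$source_integral
    bflux_acc <- bflux_acc + step$mass_budget$boundary_outflux
    if (verbose >= 2)
      message(sprintf("step %d: t=%.4f dt=%.3g cfl=%.3f", nsteps, t, dt,
                      step$cfl))
    if (!is.na(next_out) && t >= next_out - 1e-9) {
      obs[[length(obs) + 1L]] <- record(t, phases)
      if (verbose >= 1)
        message(sprintf("t=%.2f  theta_bar_c=%.5g  ratio=%.4g", t,
                        obs[[length(obs)]]$theta_bar_c,
                        obs[[length(obs)]]$ratio_M2_M1))
      next_out <- out_times[out_times > t + 1e-9][1]
      if (length(next_out) == 0) next_out <- NA
    }
  }

  structure(list(
    observables = do.call(rbind, obs),
    phases = phases, chems = chems, flow = flow,
    homeo = homeo, domain = domain, params = eff, scenario = scen, t = t,
    stats = list(n_steps = nsteps, max_flow_residual = max_resid,
                 max_cfl = max_cfl, mass_closure_error = closure_acc,
                 initial_mass = mass0,
                 final_mass = sum(vapply(tp_phases, function(ph)
                   volume_integral(domain, phases[[ph]]), numeric(1))),
                 source_integral = src_acc,
                 boundary_outflux = bflux_acc,
                 wall_time = proc.time()[["elapsed"]] - t_wall)),
    class = "tp_run")
}

# divergence of the summed chemotactic fluxes (face-averaged phase
# concentrations), the right-hand side of the mixture continuity equation
chemotaxis_divergence <- function(domain, phases, chems, params) {
  out <- rep(0, domain$n)
  n <- domain$n
  for (ph in names(tp_chemo_pairs)) {
    chi <- chemo_strength(params, ph)
    if (chi == 0) next
    J <- chems[[tp_chemo_pairs[[ph]]]]
    th <- phases[[ph]]
    if (max(th) == 0) next
    if (domain$mode == "radial_1d") {
      g <- gradient(domain, J)
      thf <- c(0, (th[-n] + th[-1]) / 2, 0)   # zero-flux at both boundaries
      out <- out + divergence(domain, chi * thf * g)
    } else {
      g <- gradient(domain, J)
      thx <- (th[domain$fx$L] + th[domain$fx$R]) / 2
      thy <- (th[domain$fy$L] + th[domain$fy$R]) / 2
      out <- out + divergence(domain, list(x = chi * thx * g$x,
                                           y = chi * thy * g$y))
    }
  }
  out
}

#' Save / load a simulation snapshot
#'
#' Snapshots are versioned JSON with every field printed via `%.17g`,
#' which round-trips IEEE doubles exactly: save followed by load is
#' bit-identical.
#'
#' @param run a `tp_run`, or a list with `t`, `phases`, `chems`.
#' @param path file path.
#' @return `path` invisibly; `load_snapshot()` returns a list with `t`,
#'   `phases`, `chems` suitable for the `restart` argument of
#'   [run_scenario()].
#' @export
save_snapshot <- function(run, path) {
  enc <- function(v) sprintf("%.17g", v)
  doc <- list(format = "tumorphase-snapshot", version = 1L,
              t = enc(run$t),
              phases = lapply(unclass(run$phases), enc),
              chems = lapply(unclass(run$chems), enc))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("snapshot format error: ",
                                           conditionMessage(e)))
  if (!identical(doc$format, "tumorphase-snapshot"))
    stop("snapshot format error: missing format marker")
  if (!identical(as.integer(doc$version), 1L))
    stop("snapshot version mismatch: ", doc$version)
  need <- function(x, what) {
    if (is.null(x)) stop("snapshot format error: missing ", what)
    x
  }
  dec <- function(v) as.numeric(v)
  phases <- lapply(need(doc$phases, "phases"), dec)
  chems <- lapply(need(doc$chems, "chems"), dec)
  if (!setequal(names(phases), tp_phases) ||
      !setequal(names(chems), tp_chemicals))
    stop("snapshot format error: truncated or incomplete field set")
  list(t = as.numeric(doc$t),
       phases = structure(phases[tp_phases], class = "tp_phase_state"),
       chems = structure(chems[tp_chemicals], class = "tp_chemical_state"))
}

#' One-parameter sweep
#'
#' Runs the same scenario for each value of one model parameter and
#' returns a tidy table of final-time observables.
#'
#' @param scen a [scenario()] object.
#' @param param parameter name (a [model_parameters()] field).
#' @param values numeric vector of parameter values.
#' @param params base parameters.
#' @return data.frame with one row per value: `param`, `value`,
#'   `theta_bar_c`, `ratio_M2_M1`, `tumor_radius` at the end time.
#' @export
sweep_parameter <- function(scen, param, values,
                            params = model_parameters()) {
  rows <- lapply(values, function(v) {
    sc <- scen
    sc$param_overrides[[param]] <- v
    run <- run_scenario(sc, params)
    tail_obs <- run$observables[nrow(run$observables), ]
    data.frame(param = param, value = v,
               theta_bar_c = tail_obs$theta_bar_c,
               ratio_M2_M1 = tail_obs$ratio_M2_M1,
               tumor_radius = tail_obs$tumor_radius)
  })
  do.call(rbind, rows)
}
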