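# Transport: upwind advection accuracy, CFL stepping, positivity, mass
# budget closure.

zero_flow <- function(d) {
  u <- lapply(stats::setNames(tp_phases, tp_phases),
              function(ph) rep(0, d$n + 1))
  structure(list(u = u, p_int = rep(0, d$n), sigma = rep(0, d$n),
                 p_cell = rep(0, d$n), residual = 0), class = "tp_flow")
}

zero_rates <- function(d) {
  z <- rep(0, d$n)
  structure(list(q_h = z, q_c = z, q_v = z, q_M1 = z, q_M1p = z, q_M2 = z,
                 q_int = z, qbar_M1 = z, extravasation = z),
            class = "tp_phase_rates")
}

test_that("zero velocities, chemotaxis and rates leave the state unchanged", {
  d <- small_domain(30)
  st <- random_valid_state(d, 1)
  ch <- chemical_state(d)           # all chemicals zero -> no chemotaxis
  step <- advance_phases(d, st$phases, zero_flow(d), ch, zero_rates(d),
                         dt = 0.05, default_params(),
                         theta_inf = list(h = 0.6, c = 0, v = 0.0175,
                                          M1 = 0, M1p = 0, M2 = 0,
                                          int = 0.3825))
  for (ph in tp_phases)
    expect_identical(step$phases[[ph]], st$phases[[ph]], label = ph)
  expect_identical(step$mass_budget$closure_error, 0)
})

test_that("radial advection converges to the characteristics solution", {
  u0 <- 0.5
  Tend <- 2
  l1 <- sapply(c(60, 120, 240), function(n) {
    d <- make_domain(list(mode = "radial_1d", R = 12, n_cells = n))
    mm <- manufactured_case("advection_bump", d)
    th <- mm$theta0
    fl <- zero_flow(d)
    fl$u <- lapply(fl$u, function(u) rep(u0, d$n + 1))
    fl$u$h[1] <- 0                                  # symmetry face
    ch <- chemical_state(d)
    inf0 <- list(h = 0, c = 0, v = 0, M1 = 0, M1p = 0, M2 = 0, int = 0)
    t <- 0
    st <- uniform_phases(d)
    st$h <- th
    while (t < Tend - 1e-12) {
      dt <- min(0.4 * d$dr / u0, Tend - t)
      step <- advance_phases(d, st, fl, ch, zero_rates(d), dt,
                             default_params(), inf0)
      st <- step$phases
      t <- t + dt
    }
    sum(d$vol * abs(st$h - mm$exact_fn(d$r_cell, Tend)))
  })
  expect_gt(log2(l1[1] / l1[2]), 0.7)     # first-order upwind
  expect_gt(log2(l1[2] / l1[3]), 0.7)
})

test_that("time step follows the CFL rule and event capping", {
  d <- small_domain(30)
  p <- default_params()
  ch <- chemical_state(d)
  fl <- zero_flow(d)
  expect_identical(compute_dt(d, fl, ch, p, dt_max = 0.1), 0.1)
  fl$u$c[10] <- 2
  expect_equal(compute_dt(d, fl, ch, p, cfl = 0.5, dt_max = 1),
               0.5 * d$dr / 2, tolerance = 1e-12)
  # an event 0.01 ahead wins over a permissive CFL bound
  expect_equal(compute_dt(d, fl, ch, p, cfl = 0.5, dt_max = 1, t = 5,
                          events = c(5.01, 7)), 0.01, tolerance = 1e-12)
  # chemotactic speeds count too
  fl <- zero_flow(d)
  chb <- chemical_state(d, b = 4 * exp(-d$r_cell))
  st <- uniform_phases(d, M2 = 0.01)
  dtc <- compute_dt(d, fl, chb, p, cfl = 0.4, dt_max = 10)
  g <- gradient(d, chb$b)
  expect_equal(dtc, 0.4 * d$dr / max(abs(p$chi_b * g)), tolerance = 1e-12)
})

test_that("upwinding keeps phases nonnegative under the CFL bound", {
  d <- small_domain(40)
  p <- default_params()
  st <- random_valid_state(d, 9)
  fl <- zero_flow(d)
  set.seed(2)
  for (ph in tp_phases)
    fl$u[[ph]] <- c(0, runif(d$n, -1, 1))
  ch <- st$chems
  inf0 <- list(h = 0.6, c = 0, v = 0.0175, M1 = 0, M1p = 0, M2 = 0,
               int = 0.3825)
  dt <- compute_dt(d, fl, ch, p, cfl = 0.4, dt_max = 0.05)
  st2 <- advance_phases(d, st$phases, fl, ch, zero_rates(d), dt, p, inf0)
  for (ph in tp_phases) expect_true(all(st2$phases[[ph]] >= 0))
  # the discrete budget identity closes to round-off
  expect_lt(abs(st2$mass_budget$closure_error), 1e-10)
})

test_that("inflow boundaries impose the far-field state", {
  d <- small_domain(30)
  p <- default_params()
  st <- uniform_phases(d, h = 0.2, int = 0.3)
  fl <- zero_flow(d)
  fl$u$h <- rep(-0.5, d$n + 1); fl$u$h[1] <- 0     # inflow everywhere
  ch <- chemical_state(d)
  inf0 <- list(h = 0.6, c = 0, v = 0, M1 = 0, M1p = 0, M2 = 0, int = 0)
  step <- advance_phases(d, st, fl, ch, zero_rates(d), 0.05, p, inf0)
  # the boundary cell receives mass at the far-field concentration
  n <- d$n
  influx <- d$area[n + 1] * 0.6 * 0.5 * 0.05 / d$vol[n]
  outflow <- d$area[n] * 0.2 * 0.5 * 0.05 / d$vol[n]
  expect_equal(step$phases$h[n], 0.2 + influx - outflow, tolerance = 1e-12)
})
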