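# Multiphase flow: quiescent limits, drag-balance closed form,
# manufactured-solution convergence.

test_that("uniform unforced states are exactly quiescent", {
  d <- small_domain(40)
  p <- default_params()
  h <- default_homeo()
  st <- uniform_phases(d, h = 0.6, v = h$theta_v0, int = h$theta_int0)
  fl <- solve_flow(d, st, p)
  for (ph in tp_phases) expect_lt(max(abs(fl$u[[ph]])), 1e-12)
  expect_lt(max(abs(fl$p_int)), 1e-12)
  expect_lt(fl$residual, 1e-10)
  # uniform state with macrophages present behaves the same
  st2 <- uniform_phases(d, h = 0.5, c = 0.05, v = 0.02, M1 = 0.01,
                        M2 = 0.01, int = 0.41)
  fl2 <- solve_flow(d, st2, p)
  for (ph in tp_phases) expect_lt(max(abs(fl2$u[[ph]])), 1e-12)
})

test_that("drag-dominated two-phase reduction matches the closed form", {
  # vanishing viscosity: momentum reduces to a drag/pressure balance with
  # linear-in-radius velocities; compare away from the thin boundary layer
  d <- make_domain(list(mode = "radial_1d", R = 10, n_cells = 200))
  mm <- manufactured_case("drag_balance", d)
  p <- model_parameters(mu = 1e-4)
  st <- uniform_phases(d, h = mm$theta1, c = mm$theta2)
  fl <- solve_flow(d, st, p,
                   body_force = list(h = mm$body_force_face))
  keep <- which(d$r_face[-1] > 0.05 * d$R & d$r_face[-1] < 0.9 * d$R)
  err1 <- max(abs(fl$u$h[-1][keep] - mm$exact_u1[keep])) /
    max(abs(mm$exact_u1))
  err2 <- max(abs(fl$u$c[-1][keep] - mm$exact_u2[keep])) /
    max(abs(mm$exact_u2))
  expect_lt(err1, 5e-3)
  expect_lt(err2, 5e-3)
  # the two active phases carry equal and opposite mass fluxes
  expect_lt(max(abs(mm$theta1 * fl$u$h[-1][keep] +
                      mm$theta2 * fl$u$c[-1][keep])) /
              max(abs(mm$theta1 * mm$exact_u1)), 1e-6)
})

test_that("manufactured viscous flow converges at design order", {
  errs <- sapply(c(40, 80, 160), function(n) {
    d <- make_domain(list(mode = "radial_1d", R = 10, n_cells = n))
    mm <- manufactured_case("stokes_poly", d)
    p <- default_params()
    st <- uniform_phases(d, h = mm$theta)
    rf <- d$r_face[-1]
    fl <- solve_flow(d, st, p,
                     continuity_rhs = mm$continuity_rhs_fn(d$r_cell),
                     body_force = list(h = mm$body_force_fn(rf)),
                     bc_stress = list(h = mm$bc_stress))
    uerr <- max(abs(fl$u$h[-1] - mm$exact_u(rf))) / max(abs(mm$exact_u(rf)))
    # pressure is defined through the same system; compare shape
    perr <- max(abs(fl$p_int - mm$exact_p(d$r_cell))) /
      max(abs(mm$exact_p(d$r_cell)))
    c(uerr, perr)
  })
  ord_u <- log2(errs[1, 1] / errs[1, 2])
  expect_gt(ord_u, 1.5)
  expect_lt(errs[1, 3], 2e-3)
  expect_lt(errs[2, 3], 2e-2)
})

test_that("interstitial boundary condition and center symmetry are imposed", {
  d <- small_domain(50)
  st <- random_valid_state(d, 5)$phases
  fl <- solve_flow(d, st, default_params())
  expect_lt(abs(fl$u$int[d$n + 1]), 1e-12)
  for (ph in tp_phases) expect_identical(fl$u[[ph]][1], 0)
  expect_lt(fl$residual, 1e-8)
})

test_that("2D solver agrees with the radial solver on symmetric states", {
  p <- default_params()
  prof <- function(r) 0.65 + 0.05 * exp(-(r / 3)^2)
  d1 <- make_domain(list(mode = "radial_1d", R = 6, n_cells = 48))
  st1 <- phase_state(d1, h = prof(d1$r_cell), v = 0.0175,
                     int = pmax(1 - prof(d1$r_cell) - 0.0175, 0))
  f1 <- solve_flow(d1, st1, p)
  d2 <- make_domain(list(mode = "cartesian_2d", R = 6, dx = 0.5))
  r2 <- sqrt(d2$x^2 + d2$y^2)
  st2 <- phase_state(d2, h = prof(r2), v = 0.0175,
                     int = pmax(1 - prof(r2) - 0.0175, 0))
  f2 <- solve_flow(d2, st2, p)
  expect_lt(f2$residual, 1e-8)
  # project 2D healthy-cell velocities onto the radial direction
  fx2 <- phase_flux(d2, st2, f2, "h")
  ur2 <- (d2$x * fx2$x + d2$y * fx2$y) / pmax(r2, 1e-9) / st2$h
  u1 <- approx(d1$r_face, f1$u$h, xout = r2, rule = 2)$y
  sel <- r2 > 0.5 & r2 < 5
  expect_lt(max(abs(ur2[sel] - u1[sel])) / max(abs(f1$u$h)), 0.2)
})

test_that("2D uniform homeostatic state is exactly quiescent", {
  p <- default_params()
  h <- default_homeo()
  d2 <- make_domain(list(mode = "cartesian_2d", R = 5, dx = 0.5))
  st <- phase_state(d2, h = 0.6, v = h$theta_v0, int = h$theta_int0)
  fl <- solve_flow(d2, st, p)
  expect_lt(max(abs(unlist(fl$u))), 1e-12)
  expect_lt(max(abs(fl$p_int)), 1e-12)
})

test_that("flow responds to the pressure closure above natural density", {
  # a compressed core (theta > theta*) must push material outward
  d <- small_domain(60)
  p <- default_params()
  bump <- 0.65 + 0.05 * exp(-(d$r_cell / 3)^2)
  st <- phase_state(d, h = bump, v = 0.0175, int = pmax(1 - bump - 0.0175, 0))
  fl <- solve_flow(d, st, p)
  mid <- round(d$n / 3)
  expect_gt(fl$u$h[mid], 0)
  # the cellular pressure p_int + Sigma is positive in the compressed core
  expect_gt(max(fl$p_int + fl$sigma), 0)
  expect_gt(max(fl$p_cell), 0)
})
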