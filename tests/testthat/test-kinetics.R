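# Reaction terms: Heaviside switch, pressure closure, cell pressure,
# phase production rates and their algebraic identities.

test_that("smoothed Heaviside matches direct evaluation and limits", {
  expect_identical(smooth_heaviside(0, 0.2), 0.5)
  expect_equal(smooth_heaviside(-0.3, 0.2), (1 + tanh(-1.5)) / 2,
               tolerance = 1e-15)
  expect_equal(smooth_heaviside(-0.3, 0.2), 0.04742587, tolerance = 1e-7)
  expect_equal(smooth_heaviside(5, 0.2), 1, tolerance = 1e-10)
  expect_equal(smooth_heaviside(-5, 0.2), 0, tolerance = 1e-10)
  y <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(smooth_heaviside(y, 0.2)) > 0))
  expect_error(smooth_heaviside(0, 0), "positive")
})

test_that("pressure closure is zero below theta* and matches the hand sum", {
  d <- small_domain(10)
  p <- default_params()
  below <- uniform_phases(d, h = 0.5, int = 0.4)       # theta = 0.5 < 0.6
  expect_identical(sigma_closure(below, p), rep(0, d$n))
  at <- uniform_phases(d, h = 0.6, int = 0.35)
  expect_equal(sigma_closure(at, p), rep(0, d$n), tolerance = 1e-12)
  # hand-summed squared deviations for theta = 0.7:
  # 3*(0.7)^2 + (0.68)^2 + (0.42)^2 + 0 = 2.1088
  st <- uniform_phases(d, h = 0.7, v = 0.02, int = 0.28)
  expect_equal(sigma_closure(st, p)[1], 0.01 / 2.1088, tolerance = 1e-6)
  # denominator guard: result insensitive to a tenfold eps_den change
  s1 <- sigma_closure(st, p, eps_den = 1e-8)
  s2 <- sigma_closure(st, p, eps_den = 1e-7)
  expect_lt(max(abs(s1 - s2)), 1e-6)
  # continuity at theta = theta*: approach from above tends to zero
  eps <- 1e-9
  near <- uniform_phases(d, h = 0.6 + eps, v = 0.02, int = 0.38)
  expect_lt(sigma_closure(near, p)[1], 1e-6)
})

test_that("cell pressure is the concentration-weighted cellular mean", {
  d <- small_domain(10)
  z <- rep(0, d$n)
  st <- uniform_phases(d, h = 0.5, c = 0.1, v = 0.02, int = 0.38)
  expect_identical(cell_pressure(st, z, z, z, z, z), z)
  # equal pressures weight by the cellular fraction over the total
  one <- rep(1, d$n)
  st2 <- uniform_phases(d, h = 0.55, c = 0.05, v = 0.02, int = 0.38)
  expect_equal(cell_pressure(st2, one, one, one, one, one),
               rep(0.6 / 1.0, d$n), tolerance = 1e-12)
  # toy weighted sum: 0.5*1 + 0.1*2 over total 1 -> 0.7
  expect_equal(cell_pressure(st, one, 2 * one, z, z, z), rep(0.7, d$n),
               tolerance = 1e-12)
})

test_that("production terms match hand-evaluated published forms", {
  d <- small_domain(10)
  p <- default_params()
  h <- default_homeo()
  # homeostatic state: healthy-cell and vessel rates vanish at the
  # converged equilibrium, and are small at the rounded printed values
  st <- uniform_phases(d, h = 0.6, v = h$theta_v0, int = h$theta_int0)
  ch <- chemical_state(d, c = h$c0, g = h$g0)
  q <- production_terms(st, ch, rep(0, d$n), p)
  expect_lt(max(abs(q$q_h)), 1e-9)
  # q_v uses the configured k_ang (published value), not the implied one,
  # so its homeostatic residual reflects that documented inconsistency
  q_v_expected <- p$k_ang * h$theta_v0 * h$g0 *
    h$theta_int0 / (p$eps + h$theta_int0) -
    p$k_occ * h$theta_v0 * smooth_heaviside(-p$p_crit, p$h_smooth)
  expect_equal(q$q_v[1], q_v_expected, tolerance = 1e-12)

  # cancer rate, hand evaluation with no macrophages
  st2 <- uniform_phases(d, c = 0.05, int = 0.3825, h = 0.55, v = 0.0175)
  ch2 <- chemical_state(d, c = 0.25)
  q2 <- production_terms(st2, ch2, rep(0, d$n), p)
  expect_equal(q2$q_c[1],
               2 * 0.05 * 0.3825 * 0.5 - 0.075 * 0.05 * (0.45 / 0.35),
               tolerance = 1e-12)
  # M1 extravasation at half-saturating CSF-1
  st3 <- uniform_phases(d, v = 0.0175, h = 0.6, int = 0.38)
  ch3 <- chemical_state(d, a = 0.25, c = 0.25)
  q3 <- production_terms(st3, ch3, rep(0, d$n), p)
  expect_equal(q3$q_M1[1], 2.0 * 0.0175 * 0.5, tolerance = 1e-12)
})

test_that("mass bookkeeping: only extravasation sources the mixture", {
  d <- small_domain(24)
  p <- default_params()
  th <- therapy_parameters(TRUE)
  for (seed in 1:5) {
    st <- random_valid_state(d, seed, with_m1p = TRUE)
    q <- production_terms(st$phases, st$chems, rep(0.1, d$n), p, th)
    total <- q$q_h + q$q_c + q$q_v + q$q_M1 + q$q_M1p + q$q_M2 + q$q_int
    expect_lt(max(abs(total - q$extravasation)), 1e-14)
    # the stated grouping identity of the interstitial balance
    expect_lt(max(abs(q$q_int + q$q_h + q$q_c + q$q_v + q$q_M2 + q$qbar_M1 -
                        th$k_d_M1p * st$phases$M1p)), 1e-14)
  }
})

test_that("macrophages shift the cancer rate in opposite directions", {
  d <- small_domain(10)
  p <- default_params()
  base <- uniform_phases(d, c = 0.1, h = 0.4, int = 0.38, v = 0.0175)
  ch <- chemical_state(d, c = 0.25)
  q0 <- production_terms(base, ch, rep(0, d$n), p)$q_c[1]
  withM2 <- uniform_phases(d, c = 0.1, h = 0.4, int = 0.38, v = 0.0175,
                           M2 = 0.05)
  withM1 <- uniform_phases(d, c = 0.1, h = 0.4, int = 0.38, v = 0.0175,
                           M1 = 0.05)
  expect_gt(production_terms(withM2, ch, rep(0, d$n), p)$q_c[1], q0)
  expect_lt(production_terms(withM1, ch, rep(0, d$n), p)$q_c[1], q0)
  # occlusion increases with cell pressure
  st <- uniform_phases(d, v = 0.0175, h = 0.6, int = 0.38)
  qlo <- production_terms(st, ch, rep(0.1, d$n), p)$q_v[1]
  qhi <- production_terms(st, ch, rep(0.5, d$n), p)$q_v[1]
  expect_lt(qhi, qlo)
})

test_that("therapy terms vanish bit-for-bit without drug or bound cells", {
  d <- small_domain(24)
  p <- default_params()
  st <- random_valid_state(d, 42)           # M1p = 0, d = 0
  q_off <- production_terms(st$phases, st$chems, rep(0.2, d$n), p,
                            therapy_parameters(FALSE))
  q_on <- production_terms(st$phases, st$chems, rep(0.2, d$n), p,
                           therapy_parameters(TRUE))
  for (nm in names(q_off))
    expect_identical(q_off[[nm]], q_on[[nm]], label = nm)
  # negative concentrations are rejected (clipping is the caller's duty)
  bad <- st$phases
  bad$c[1] <- -1e-3
  expect_error(production_terms(bad, st$chems, rep(0, d$n), p), "negative")
})
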