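# Quasi-steady species: source forms, uniform-state oracles, maximum
# principle, linearity, dosing schedule.

test_that("source terms match hand-evaluated published forms", {
  d <- small_domain(10)
  p <- default_params()
  # no cancer, no TGF-beta: the TGF-beta source vanishes entirely
  st <- uniform_phases(d, h = 0.6, v = 0.0175, int = 0.3825)
  ch <- chemical_state(d, c = 0.25)
  s <- chemical_sources(st, ch, 0, p)
  expect_identical(s$f, rep(0, d$n))
  # CXCL12 production from the vasculature alone
  expect_equal(s$b[1], 0.54806 * 0.0175, tolerance = 1e-12)
  expect_equal(s$b[1], 9.591e-3, tolerance = 1e-3)
  # homeostatic oxygen and VEGF sources vanish at the converged values
  h <- default_homeo()
  st0 <- uniform_phases(d, h = 0.6, v = h$theta_v0, int = h$theta_int0)
  ch0 <- chemical_state(d, c = h$c0, g = h$g0)
  s0 <- chemical_sources(st0, ch0, 0, p)
  expect_lt(max(abs(s0$c)), 1e-10)
  expect_lt(max(abs(s0$g)), 1e-10)
})

test_that("uniform phases give uniform fields equal to the scalar source root", {
  d <- small_domain(24)
  p <- default_params()
  th <- therapy_parameters(TRUE, t0_pill = 0)
  for (seed in 1:4) {
    set.seed(100 + seed)
    st <- uniform_phases(d, h = runif(1, 0.3, 0.6), c = runif(1, 0, 0.2),
                         v = runif(1, 0.005, 0.03), M1 = runif(1, 0, 0.05),
                         M2 = runif(1, 0, 0.05), int = runif(1, 0.2, 0.4))
    cc <- solve_quasi_steady(d, "c", st, p, th)
    expect_lt(diff(range(cc)), 1e-9)
    # independent oracle: bisection on the pointwise oxygen source
    sfun <- function(x) chemical_sources(
      st, chemical_state(d, c = x), 0, p)$c[1]
    root <- uniroot(sfun, c(0, 1), tol = 1e-14)$root
    expect_equal(cc[1], root, tolerance = 1e-8)
    for (sp in c("g", "a", "b", "l", "f", "d")) {
      J <- solve_quasi_steady(d, sp, st, p, th, t = 1, c_field = cc)
      expect_lt(diff(range(J)), max(J, 1) * 1e-9)
      sfun <- function(x) {
        chj <- chemical_state(d, c = cc[1])
        chj[[sp]] <- rep(x, d$n)
        chemical_sources(st, chj, 1, p, th)[[sp]][1]
      }
      root <- uniroot(sfun, c(0, 50), tol = 1e-14, extendInt = "downX")$root
      expect_equal(J[1], root, tolerance = 1e-8, label = sp)
    }
  }
})

test_that("oxygen respects the maximum principle on random states", {
  d <- small_domain(40)
  p <- default_params()
  for (seed in 1:6) {
    st <- random_valid_state(d, seed)
    cc <- solve_quasi_steady(d, "c", st$phases, p)
    expect_true(all(cc >= -1e-12))
    expect_true(all(cc <= 1 + 1e-9))
  }
})

test_that("solutions are linear in the production coefficient", {
  d <- small_domain(30)
  st <- random_valid_state(d, 7)
  p1 <- default_params()
  p2 <- model_parameters(k_p_b = 2 * p1$k_p_b)
  cc <- solve_quasi_steady(d, "c", st$phases, p1)
  b1 <- solve_quasi_steady(d, "b", st$phases, p1, c_field = cc)
  b2 <- solve_quasi_steady(d, "b", st$phases, p2, c_field = cc)
  expect_equal(b2, 2 * b1, tolerance = 1e-10)
})

test_that("discrete elliptic residuals vanish at the solution", {
  d <- small_domain(40)
  p <- default_params()
  th <- therapy_parameters(TRUE, t0_pill = 0)
  st <- random_valid_state(d, 3, with_m1p = TRUE)
  ch <- solve_all_chemicals(d, st$phases, p, th, t = 2)
  L <- lapply(stats::setNames(tp_chemicals, tp_chemicals), function(sp) {
    D <- switch(sp, c = p$D_c, g = p$D_g, a = p$D_a, b = p$D_b,
                l = p$D_l, f = p$D_f, d = th$D_d)
    laplacian_operator(d, D)
  })
  s <- chemical_sources(st$phases, ch, 2, p, th)
  for (sp in tp_chemicals) {
    resid <- as.numeric(L[[sp]] %*% ch[[sp]]) + s[[sp]]
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("vascular drug concentration follows the pulsed schedule", {
  th <- therapy_parameters(TRUE)
  expect_identical(drug_vascular_concentration(0, th), 0)
  expect_identical(drug_vascular_concentration(99.999, th), 0)
  expect_equal(drug_vascular_concentration(100, th), 1, tolerance = 1e-12)
  # just before and just after the second dose
  expect_equal(drug_vascular_concentration(100.5 - 1e-12, th), exp(-2.4),
               tolerance = 1e-6)
  expect_equal(drug_vascular_concentration(100.5, th), 1 + exp(-2.4),
               tolerance = 1e-6)
  expect_equal(drug_vascular_concentration(100.5, th), 1.0907,
               tolerance = 1e-4)
  # superposition stays below the geometric-series bound
  tt <- seq(100, 110, by = 0.01)
  dv <- drug_vascular_concentration(tt, th)
  expect_true(all(dv <= 1 / (1 - exp(-4.8 * 0.5)) + 1e-12))
  expect_true(all(dv >= 0))
  # no pills, no drug
  expect_identical(drug_vascular_concentration(150,
    therapy_parameters(TRUE, N_pills = 0)), 0)
})

test_that("drug field is identically zero before treatment and without pills", {
  d <- small_domain(20)
  p <- default_params()
  st <- random_valid_state(d, 11)
  th <- therapy_parameters(TRUE)
  dd <- solve_quasi_steady(d, "d", st$phases, p, th, t = 50)
  expect_identical(dd, rep(0, d$n))
})
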