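# Parameter defaults, validation, configuration loading, serialization.

test_that("defaults reproduce the published dimensionless constants", {
  p <- default_params()
  printed <- list(
    k_m_h = 1.0, k_m_c = 2.0, k_d_h = 0.15, k_d_c = 0.075,
    c_p = 0.25, c_c1 = 0.2, c_c2 = 0.1, c_a = 0.05,
    k_c_h = 0.01, k_c_c = 0.01, k_cm_h = 0.1, k_cm_c = 0.2,
    k_occ = 0.1, p_crit = 0.3, eps = 0.01, h_smooth = 0.2,
    Lambda = 0.1, theta_star = 0.6, k_ang = 4.87e-3,
    D_c = 1.0, D_g = 0.05, D_a = 0.11, D_b = 0.001, D_l = 0.11, D_f = 0.5,
    k_p_g = 0.00959, k_d_g = 0.0264, k_assoc_g = 6.57e-6,
    k_p_a = 0.00959, k_d_a = 0.0216, k_assoc_a = 8.75e-6,
    k_p_b = 0.54806, k_d_b = 2.273e-3, k_assoc_b = 7e-6,
    k_p_l = 0.00959, k_d_l = 0.0216, k_assoc_l = 6.93e-6,
    k_p_f = 0.00959, k_d_f = 0.436, k_assoc_f = 7e-6,
    theta_M = 0.1, k_c_M1 = 0.2, k_c_M2 = 5.0,
    k_d_M1 = 0.075, k_d_M2 = 0.075, k_aa = 0.5, k_ext_M1 = 2.0,
    a_p = 0.25, f_p = 0.015,
    chi_g = 0.14, chi_a = 0.14, chi_l = 0.14,
    c_v_ref = 1.0, k_rep = 1.0)
  for (nm in names(printed))
    expect_identical(p[[nm]], printed[[nm]], label = nm)
  expect_equal(p$chi_b, 0.7, tolerance = 1e-15)
  expect_identical(unname(p$mu), rep(10, 7))
  expect_identical(unique(p$d_drag[upper.tri(p$d_drag)]), 1)
  # derived defaults follow their stated couplings
  expect_identical(p$k_cm_c, p$k_cm_h * p$k_m_c)
  expect_identical(p$chi_b, 5 * p$chi_a)
})

test_that("therapy defaults match the immunotherapy table", {
  th <- therapy_parameters()
  expect_false(th$enabled)
  expect_identical(th$k_d_M1p, 0.075)
  expect_identical(th$k_d_M1p, default_params()$k_d_M1)
  expect_identical(th$D_d, 0.231)
  expect_identical(th$d_p, 3e-3)
  expect_identical(th$k_rep_d, 0.25)
  expect_identical(th$k_d_d, 0.016)
  expect_identical(th$k_assoc_d, 0.016)
  expect_identical(th$k_assoc_M1, 2.0)
  expect_identical(th$k_el_d, 4.8)
  expect_identical(th$T_pill, 0.5)
  expect_identical(th$t0_pill, 100)
  expect_identical(th$N_pills, 10L)
  expect_identical(th$d_max, 1.0)
})

test_that("overrides change only the named field and invariants are enforced", {
  p <- model_parameters(k_aa = 2.5)
  expect_identical(p$k_aa, 2.5)
  base <- default_params()
  for (nm in setdiff(names(base), c("k_aa", "mu", "d_drag")))
    expect_identical(p[[nm]], base[[nm]], label = nm)
  expect_error(model_parameters(c_c2 = 0.3), "c_c1 > c_c2")
  expect_error(model_parameters(k_m_c = 0.5), "k_m_c > k_m_h")
  expect_error(model_parameters(k_d_c = 0.2), "k_d_c < k_d_h")
  expect_error(model_parameters(h_smooth = 0), "h_smooth")
  expect_error(model_parameters(k_aa = -1), "nonnegative")
  expect_error(model_parameters(nonsense = 1), "unknown parameter")
  expect_error(therapy_parameters(N_pills = 2.5), "N_pills")
  expect_error(therapy_parameters(T_pill = 0), "T_pill")
})

test_that("serialization round-trips every field exactly", {
  p <- model_parameters(k_aa = 1 / 3, chi_b = 0.123456789012345)
  q <- params_deserialize(params_serialize(p))
  expect_identical(params_as_list_public(p), params_as_list_public(q))
  th <- therapy_parameters(TRUE, k_el_d = pi)
  th2 <- params_deserialize(params_serialize(th))
  expect_identical(unclass(th), unclass(th2))
})

test_that("configuration documents load with defaults, overrides, errors", {
  cfg <- load_config("")
  expect_identical(cfg$params$k_m_c, 2.0)
  expect_identical(cfg$params$k_aa, 0.5)
  cfg <- load_config("parameters: {k_aa: 2.5}")
  expect_identical(cfg$params$k_aa, 2.5)
  expect_identical(cfg$params$k_m_c, 2.0)
  expect_error(load_config("parameters: {c_c2: 0.3}"), "c_c1 > c_c2")
  expect_error(load_config("bogus_section: 1"), "bogus_section")
  expect_error(load_config("scenario: {bogus: 1}"), "bogus")
  # JSON is accepted too, and scenario fields propagate
  cfg <- load_config('{"scenario": {"t_end": 25, "macrophage_mode": "inert"}}')
  expect_identical(cfg$scenario$t_end, 25L)
  expect_identical(cfg$scenario$macrophage_mode, "inert")
  # therapy section reaches the scenario
  cfg <- load_config("therapy: {enabled: yes, N_pills: 4}")
  expect_true(cfg$scenario$therapy$enabled)
  expect_identical(cfg$scenario$therapy$N_pills, 4L)
})

test_that("scenario modes restrict the effective rates", {
  base <- default_params()
  sc <- function(mode) scenario(macrophage_mode = mode, t_end = 1)
  expect_identical(effective_parameters(base, sc("both"))$k_aa, 0.5)
  expect_identical(effective_parameters(base, sc("m1_only"))$k_aa, 0)
  inert <- effective_parameters(base, sc("inert"))
  expect_identical(inert$k_c_M1, 0)
  expect_identical(inert$k_c_M2, 0)
  expect_identical(inert$k_aa, 0.5)
  expect_identical(effective_parameters(base, sc("none"))$k_ext_M1, 0)
})
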