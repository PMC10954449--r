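test_that("zippering probability follows the alpha / (alpha + exp(dG/RT)) form", {
  expect_equal(p_zippering(0, 0.25), 0.2)
  expect_equal(p_zippering(Inf, 0.25), 0)
  expect_equal(p_zippering(-6.45, 4.3e-5), 0.70, tolerance = 0.01)
  expect_equal(p_zippering(-50, 1e-6), 1, tolerance = 1e-6)
  expect_equal(p_zippering(0, 1e9), 1, tolerance = 1e-9)
  expect_equal(p_zippering(c(-1, Inf, 2), Inf), c(1, 0, 1))
  # the alpha substitution reproduces the two-rate competition form
  set.seed(4)
  for (r in 1:20) {
    kzip <- 10^runif(1, 3, 8); kdiss <- 10^runif(1, 3, 8)
    dg <- runif(1, -5, 5)
    direct <- kzip / (kzip + kdiss * exp(dg / RT25))
    expect_equal(p_zippering(dg, kzip / kdiss), direct, tolerance = 1e-12)
  }
})

test_that("predicted k_on equals the brute-force site sum and behaves in limits", {
  d <- hk_test_duplex("t12")
  model <- kinetic_model_params(2.2e6, 3, list(perfect = 0.01))
  sites <- enumerate_sites(d, 3, finite_only = FALSE)
  oracle <- 2.2e6 * sum(p_zippering(sites$dG, 0.01))
  expect_equal(predict_kon(d, model), oracle, tolerance = 1e-12)

  # alpha -> 0 sends the prediction to zero
  tiny <- kinetic_model_params(2.2e6, 3, list(perfect = 1e-12))
  expect_lt(predict_kon(d, tiny), 1)

  # zippering-dominant limit counts the finite-dG sites
  sat <- kinetic_model_params(2.2e6, 3, list(perfect = Inf))
  expect_equal(predict_kon(d, sat), 2.2e6 * sum(is.finite(sites$dG)))
})

test_that("k_on prediction is invariant under strand-role swap", {
  model <- kinetic_model_params(2e6, 3, list(perfect = 0.05,
                                             single_mismatch = 1e-4))
  for (nm in c("t12", "m_4")) {
    d <- hk_test_duplex(nm)
    expect_equal(predict_kon(swap_strands(d), model), predict_kon(d, model),
                 tolerance = 1e-9)
  }
})

test_that("removing nucleation sites never increases predicted k_on", {
  # dropping any subset of finite-dG sites (a defect inside a site sends its
  # dG to infinity) can only lower the site sum at fixed parameters
  dups <- hk_test_panel_duplexes()
  model <- kinetic_model_params(2e6, 3, list(perfect = 0.02))
  d <- dups[["t12"]]
  sites <- enumerate_sites(d, 3)
  kon0 <- predict_kon(d, model, sites = sites)
  set.seed(19)
  for (r in 1:10) {
    keep <- sites[runif(nrow(sites)) > 0.3, ]
    expect_lte(predict_kon(d, model, sites = keep), kon0 + 1e-9)
  }
  # on the pairing register itself, every defect removes in-register sites:
  # the in-register site sum never exceeds the perfect duplex's
  alpha <- list(perfect = 0.02, single_mismatch = 0.02,
                double_mismatch = 0.02, bulge = 0.02)
  model_all <- kinetic_model_params(2e6, 3, alpha)
  reg0 <- predict_kon(d, model_all, sites = sites[sites$in_register, ])
  for (nm in setdiff(names(dups), "t12")) {
    s <- enumerate_sites(dups[[nm]], 3)
    expect_lte(predict_kon(dups[[nm]], model_all,
                           sites = s[s$in_register, ]), reg0 + 1e-9)
  }
})

test_that("k_off follows exactly from K_D and k_on", {
  expect_equal(koff_from_kd(1e-9, 1e7), 1e-2)
  expect_equal(koff_from_kd(1, 1), 1)
  expect_error(koff_from_kd(-1, 1), "positive")
  # defect raises k_off by the K_D ratio times the k_on ratio
  dups <- hk_test_panel_duplexes()
  model <- kinetic_model_params(2e6, 3, list(perfect = 0.02,
                                             single_mismatch = 1e-4))
  k0 <- koff_from_kd(kd_at(dups[["t12"]]), predict_kon(dups[["t12"]], model))
  k4 <- koff_from_kd(kd_at(dups[["m_4"]]), predict_kon(dups[["m_4"]], model))
  ratio <- (kd_at(dups[["m_4"]]) / kd_at(dups[["t12"]])) *
    (predict_kon(dups[["m_4"]], model) / predict_kon(dups[["t12"]], model))
  expect_equal(k4 / k0, ratio, tolerance = 1e-9)
})

test_that("the shared-k_nuc fit recovers generating parameters from noisy rates", {
  dups <- hk_test_panel_duplexes()
  true <- kinetic_model_params(2.2e6, 3,
                               list(perfect = 5e-3, single_mismatch = 4.3e-5,
                                    double_mismatch = 4.6e-5, bulge = 5e-3))
  kon_true <- vapply(dups, predict_kon, numeric(1), model = true)
  set.seed(42)
  kon_obs <- kon_true * exp(rnorm(length(kon_true), 0, 0.05))
  fit <- fit_nucleation(dups, kon_obs, seed = 9, n_boot = 30)
  expect_lt(abs(log10(coef(fit)[["k_nuc"]]) - log10(2.2e6)), 0.1)
  for (cl in c("single_mismatch", "double_mismatch")) {
    a_hat <- coef(fit)[[paste0("alpha_", cl)]]
    a_true <- true$alpha_by_class[[cl]]
    expect_lt(abs(log10(a_hat / a_true)), log10(2))
  }
})

test_that("saturated alpha is reported as a lower bound, degenerate designs error", {
  dups <- hk_test_panel_duplexes()
  # generate with alpha so large that p ~ 1 for the mismatch classes too:
  # only a lower bound is then identifiable
  sat <- kinetic_model_params(2e6, 3, list(perfect = 50, single_mismatch = 50,
                                           double_mismatch = 50, bulge = 50))
  kon_true <- vapply(dups, predict_kon, numeric(1), model = sat)
  fit <- fit_nucleation(dups, kon_true, seed = 2, n_boot = 0)
  expect_true(all(fit$alpha_lower_bound))

  perfect_only <- dups[rep("t12", 4)]
  expect_error(fit_nucleation(perfect_only, kon_true[rep(1, 4)], n_boot = 0),
               "2 defect classes")
})

test_that("with all alphas fixed the shared k_nuc is the closed-form solution", {
  dups <- hk_test_panel_duplexes()[c("t12", "t12", "m_4", "m_4")]
  model <- kinetic_model_params(3e6, 3, list(perfect = 0.02,
                                             single_mismatch = 1e-4))
  kon <- vapply(dups, predict_kon, numeric(1), model = model)
  fixed <- c(perfect = 0.02, single_mismatch = 1e-4)
  fit <- fit_nucleation(dups, kon, n_boot = 0, alpha_fixed = fixed)
  expect_equal(coef(fit)[["k_nuc"]], 3e6, tolerance = 1e-10)
})

test_that("log k_off regresses linearly on pairing free energy", {
  set.seed(8)
  dg <- runif(30, -18, -6)
  koff_exact <- 1e12 * exp(0.9 * dg / RT25)
  r <- suppressWarnings(log_koff_vs_dg(dg, koff_exact))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.9 / (RT25 * log(10)), tolerance = 1e-9)

  noisy <- koff_exact * exp(rnorm(30, 0, 0.1))
  expect_gt(log_koff_vs_dg(dg, noisy)$r_squared, 0.9)
  expect_error(log_koff_vs_dg(dg[1:2], koff_exact[1:2]), "3 records")
})
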