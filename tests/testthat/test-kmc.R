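test_that("the chain state space counts all contiguous bound intervals", {
  cfg <- kmc_config(n_trajectories = 10)
  ch12 <- build_chain(hk_test_duplex("t12"), cfg)
  expect_equal(nrow(ch12$states), 78L)   # 12*13/2 intervals (+1 dissociated)
  expect_equal(ch12$id_diss, 79L)

  d2 <- duplex(hk_seq("GC"), hk_seq("GC"))
  ch2 <- build_chain(d2, cfg)
  expect_equal(nrow(ch2$states) + 1L, 4L)
})

test_that("interval free energies equal the NN engine on the sub-duplex", {
  cfg <- kmc_config()
  d <- hk_test_duplex("t12")
  ch <- build_chain(d, cfg)
  # fully zipped interval equals the full duplex free energy
  full <- which(ch$states$a == 1 & ch$states$b == 12)
  expect_equal(ch$G[full], duplex_thermo(d, 25)$dG, tolerance = 1e-12)
  # an interior 3-pair interval equals the free-standing 3-mer duplex
  s <- which(ch$states$a == 5 & ch$states$b == 7)
  sub <- duplex(hk_seq(substr(d$a$bases, 6, 8)),
                hk_seq(substr(d$b$bases, 5, 7)))
  expect_equal(ch$G[s], duplex_thermo(sub, 25)$dG, tolerance = 1e-12)
})

test_that("Metropolis rates: downhill at k_uni, uphill Boltzmann-suppressed, balanced", {
  cfg <- kmc_config()
  ch <- build_chain(hk_test_duplex("t12"), cfg)
  e <- ch$edges
  downhill <- e$dG_grow <= 0 & !e$mm
  expect_true(all(abs(e$rate_grow[downhill] - 4.2e8) < 1e-3))
  # an uphill move of +2.49 kcal/mol would run at ~6.3e6/s
  expect_equal(4.2e8 * exp(-2.49 / RT25), 6.3e6, tolerance = 0.01)
  # detailed balance on every edge, including mismatch-barrier edges
  for (ch2 in list(ch, build_chain(hk_test_duplex("m_6"), cfg))) {
    ee <- ch2$edges[ch2$edges$to != ch2$id_diss, ]
    expect_equal(ee$rate_grow / ee$rate_shrink, exp(-ee$dG_grow / RT25),
                 tolerance = 1e-9)
  }
})

test_that("stochastic first-step estimates agree with the exact absorbing chain", {
  pan <- hk_test_panel()
  seqs <- list(hk_seq("CAC"), hk_seq("CACG"), hk_seq("CACGCA"))
  for (k in seq_along(seqs)) {
    b <- seqs[[k]]
    d <- duplex(reverse_complement(b), b)
    cfg <- kmc_config(n_trajectories = 1e4, seed = 20 + k)
    ch <- build_chain(d, cfg)
    ep <- exact_passage(ch)
    fs <- simulate_first_step(ch, cfg)
    p_exact <- mean(ep$p_success)  # uniform start-site draw
    expect_lt(abs(fs$p_success - p_exact), 3 * fs$se_p + 1e-12)
  }
  # a mismatched short duplex too
  defs <- list(defect("mismatch", 3))
  b6 <- hk_seq("CACGCA")
  d6 <- duplex(make_variant(reverse_complement(b6), b6, defs), b6, defs)
  cfg <- kmc_config(n_trajectories = 1e4, seed = 31)
  ch6 <- build_chain(d6, cfg)
  expect_lt(abs(simulate_first_step(ch6, cfg)$p_success -
                  mean(exact_passage(ch6)$p_success)),
            3 * sqrt(0.25 / 1e4) * 3)
})

test_that("first-step k_on lands near k_coll times the success probability", {
  cfg <- kmc_config(n_trajectories = 4000, seed = 5, k_nuc_bi = 2e6)
  ch <- build_chain(hk_test_duplex("t12"), cfg)
  fs <- simulate_first_step(ch, cfg)
  expect_equal(fs$k_on, fs$k_coll * fs$p_success, tolerance = 1e-3)
  expect_gt(fs$k_on, 0.5e7)   # order 1e7 at the fitted entry scale
  expect_lt(fs$k_on, 5e7)
  # reproducibility under a fixed seed
  fs2 <- simulate_first_step(ch, cfg)
  expect_identical(fs$k_on, fs2$k_on)
})

test_that("a growing mismatch barrier suppresses zippering across the defect", {
  cfg <- kmc_config()
  ch <- build_chain(hk_test_duplex("m_6"), cfg)
  mm_pos <- which(ch$mismatch)
  p_prev <- NULL
  for (barrier in c(0, 2.49, 6, 12)) {
    ep <- exact_passage(ch, barrier = barrier)
    p_cross <- mean(ep$p_success[ep$pos < mm_pos])
    if (!is.null(p_prev)) expect_lt(p_cross, p_prev + 1e-12)
    p_prev <- p_cross
  }
})

test_that("the ergodic chain occupancy matches Boltzmann weights", {
  b4 <- hk_seq("CAGC")
  ch <- build_chain(duplex(reverse_complement(b4), b4), kmc_config())
  occ <- kmc_equilibrium_occupancy(ch, n_steps = 2e5, seed = 3)
  expect_equal(sum(occ$occupancy), 1, tolerance = 1e-9)
  # chi-square-style discrepancy over states with non-negligible weight
  big <- occ$boltzmann > 1e-4
  chisq <- sum((occ$occupancy[big] - occ$boltzmann[big])^2 /
                 occ$boltzmann[big])
  expect_lt(chisq, 0.01)
})

test_that("the two-parameter KMC fit recovers the zippering barrier", {
  pan <- hk_test_panel()
  nms <- c("t12", "m_4", "m_6", "m_9", "m_4,9", "m_2,11", "b_5")
  dups <- lapply(nms, hk_test_duplex)
  cfg <- kmc_config()
  kon_true <- vapply(dups, function(d)
    2e6 * sum(exact_passage(build_chain(d, cfg), barrier = 2.49)$p_success),
    numeric(1))
  set.seed(3)
  kon_obs <- kon_true * exp(rnorm(length(kon_true), 0, 0.02))
  fit <- fit_kmc(dups, kon_obs, cfg)
  expect_lt(abs(fit$mismatch_barrier - 2.49), 0.3)
  expect_lt(abs(log10(fit$k_nuc_bi / 2e6)), 0.1)

  # with no mismatched records the barrier is unidentifiable
  dup_nomm <- lapply(c("t12", "b_5", "b_7"), hk_test_duplex)
  fit2 <- fit_kmc(dup_nomm, kon_true[c(1, 7, 7)], cfg)
  expect_false(fit2$barrier_identifiable)
  expect_true(is.na(fit2$mismatch_barrier))
})
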