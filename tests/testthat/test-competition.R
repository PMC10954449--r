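test_that("the kinetic partition gives the limiting initial accuracies", {
  expect_equal(theta_in(1e7, 1e7), 0.5)
  expect_equal(theta_in(9e6, 1e6), 0.9)
  expect_equal(theta_in(1e7, 1e-9), 1, tolerance = 1e-12)
  expect_error(theta_in(0, 1e7), "positive")
})

test_that("the competitive-binding equilibrium solves exactly", {
  eq <- equilibrium_accuracy(KD_TP = 1e-9, KD_CP = 1e-9,
                             conc_T = 2e-7, conc_C = 2e-7, conc_P = 2e-7)
  expect_equal(eq$theta_eq, 0.5, tolerance = 1e-9)

  eq2 <- equilibrium_accuracy(KD_TP = 1e-12, KD_CP = 1,
                              conc_T = 2e-7, conc_C = 2e-7, conc_P = 1e-7)
  expect_equal(eq2$theta_eq, 1, tolerance = 1e-6)

  # species satisfy the mass-action relations and conservation
  eq3 <- equilibrium_accuracy(KD_TP = 1e-9, KD_CP = 1e-7,
                              conc_T = 2e-7, conc_C = 3e-7, conc_P = 2.5e-7)
  expect_equal(eq3$T * eq3$P / eq3$TP, 1e-9, tolerance = 1e-9)
  expect_equal(eq3$C * eq3$P / eq3$CP, 1e-7, tolerance = 1e-7)
  expect_equal(eq3$P + eq3$TP + eq3$CP, 2.5e-7, tolerance = 1e-15)
})

test_that("the RNA m_4,9 mixture is predicted fully accurate at equilibrium", {
  pan <- t12_panel("RNA")
  rp <- pan$probe
  kd_tp <- kd_at(duplex(pan$target, rp))
  d49 <- duplex(pan$double_mismatch[["m_4,9"]], rp, pan$defects[["m_4,9"]])
  kd_cp <- kd_at(d49)
  eq <- equilibrium_accuracy(KD_TP = kd_tp, KD_CP = kd_cp,
                             conc_T = 1e-6, conc_C = 1e-6, conc_P = 1e-6)
  expect_equal(round(eq$theta_eq, 2), 1.00)
})

test_that("mass-action integration reproduces closed forms and conserves strands", {
  # equal-concentration irreversible bimolecular closed form
  sys <- mixture_system(1e-6, 0, 1e-6, kon_TP = 1e7, koff_TP = 0,
                        kon_CP = 1, koff_CP = 0)
  tg <- seq(0, 2, length.out = 100)
  tc <- simulate_mixture(sys, tg)
  closed <- 1 - 1 / (1 + 1e7 * 1e-6 * tg)
  expect_equal(tc$TP / 1e-6, closed, tolerance = 1e-6)

  # conservation of each strand family
  sys2 <- mixture_system(2e-7, 2e-7, 2e-7, 1e7, 1e-5, 8e6, 1e-3,
                         substrate = 1e-5, k_react_TP = 50, k_react_CP = 50)
  tc2 <- simulate_mixture(sys2, c(0, 10^seq(-3, 5, length.out = 200)))
  expect_lt(max(abs(tc2$T + tc2$TP + tc2$TPr - 2e-7)) / 2e-7, 1e-9)
  expect_lt(max(abs(tc2$C + tc2$CP + tc2$CPr - 2e-7)) / 2e-7, 1e-9)
  expect_lt(max(abs(tc2$P + tc2$TP + tc2$CP + tc2$TPr + tc2$CPr - 2e-7)) /
              2e-7, 1e-9)
  expect_true(all(tc2$theta[tc2$TP + tc2$CP > 0] >= 0 &
                    tc2$theta[tc2$TP + tc2$CP > 0] <= 1))
})

test_that("theta(t) runs from the kinetic partition to the exact equilibrium", {
  sys <- mixture_system(2e-7, 2e-7, 2e-7, kon_TP = 1e7, koff_TP = 1e-5,
                        kon_CP = 8e6, koff_CP = 1e-3)
  tg <- c(0, 10^seq(-4, 5.5, length.out = 400))
  tc <- simulate_mixture(sys, tg)
  # before strand depletion sets in (t ~ a tenth of the binding half-time)
  # theta matches the rate-partition approximation
  t_early <- 1 / (10 * 1e7 * 2e-7)
  th_early <- approx(tc$time, tc$theta, xout = t_early)$y
  expect_equal(th_early, theta_in(1e7, 8e6), tolerance = 0.02)
  # late theta matches the equilibrium solver within 1%
  eq <- equilibrium_accuracy(sys)
  hl <- equilibration_halflife(tc)
  i_late <- which(tg >= 20 * hl)[1]
  expect_equal(tc$theta[i_late], eq$theta_eq, tolerance = 0.01)

  # with k_off = 0 and sub-stoichiometric probe (no competing-strand
  # depletion) the partition freezes exactly at theta_in
  sys0 <- mixture_system(2e-7, 2e-7, 2e-9, 1e7, 0, 8e6, 0)
  tc0 <- simulate_mixture(sys0, c(0, 10^seq(-3, 4, length.out = 100)))
  expect_equal(tail(tc0$theta, 1), theta_in(1e7, 8e6), tolerance = 1e-3)
  # at equimolar concentrations depletion skews the frozen partition only
  # mildly away from the approximation
  sys1 <- mixture_system(2e-7, 2e-7, 2e-7, 1e7, 0, 8e6, 0)
  tc1 <- simulate_mixture(sys1, c(0, 10^seq(-3, 4, length.out = 100)))
  expect_equal(tail(tc1$theta, 1), theta_in(1e7, 8e6), tolerance = 0.05)
})

test_that("equilibration half-life tracks the competitor off-rate", {
  # recapture-dominant design (excess target): nearly every released probe
  # rebinds the target, so C:P decays at its own off-rate
  sys <- mixture_system(4e-7, 2e-7, 2e-7, kon_TP = 1e7, koff_TP = 1e-6,
                        kon_CP = 1e5, koff_CP = 1e-2)
  tg <- c(0, 10^seq(-3, 4, length.out = 500))
  hl <- equilibration_halflife(simulate_mixture(sys, tg))
  expect_equal(hl, log(2) / 1e-2, tolerance = 0.15)

  # a single-exponential synthetic decay has half-life ln2/lambda exactly
  lam <- 0.05
  fake <- data.frame(time = tg, CP = 1e-7 * exp(-lam * tg))
  class(fake) <- c("hk_timecourse", "data.frame")
  expect_equal(equilibration_halflife(fake, cp_eq = 0), log(2) / lam,
               tolerance = 0.02)

  # no transient -> error
  flat <- data.frame(time = tg, CP = rep(1e-8, length(tg)))
  class(flat) <- c("hk_timecourse", "data.frame")
  expect_error(equilibration_halflife(flat, cp_eq = 1e-8), "equilibrium")
})

test_that("displacement accelerates equilibration but leaves equilibrium unchanged", {
  base <- list(conc = 2e-7, kon_TP = 1e7, koff_TP = 1e-5, kon_CP = 8e6,
               koff_CP = 1e-4)
  tg <- c(0, 10^seq(-3, 6, length.out = 300))
  sys_off <- mixture_system(2e-7, 2e-7, 2e-7, 1e7, 1e-5, 8e6, 1e-4)
  sys_on <- mixture_system(2e-7, 2e-7, 2e-7, 1e7, 1e-5, 8e6, 1e-4, k_sd = 10)
  end_off <- tail(simulate_mixture(sys_off, tg)$theta, 1)
  end_on <- tail(simulate_mixture(sys_on, tg)$theta, 1)
  eq <- equilibrium_accuracy(sys_off)$theta_eq
  expect_equal(end_off, eq, tolerance = 1e-3)
  expect_equal(end_on, eq, tolerance = 1e-3)
  # consistency of the derived reverse rate
  expect_equal(sys_on$k_sd / sys_on$k_sd_rev, sys_on$KD_CP / sys_on$KD_TP,
               tolerance = 1e-12)
})

test_that("reaction yields capture the transient-substrate window", {
  tg <- c(0, 10^seq(-2, 5, length.out = 300))
  mk <- function(k_react) {
    mixture_system(2e-7, 2e-7, 2e-7, 1e7, 1e-6, 8e6, 1e-3,
                   substrate = 1e-4, k_react_TP = k_react,
                   k_react_CP = k_react)
  }
  # very fast reaction captures everything initially bound as C:P
  fast <- reaction_yields(mk(1e6), tg)
  theta0 <- theta_in(1e7, 8e6)
  expect_equal(tail(fast$reacted_C, 1), 1 - theta0, tolerance = 0.05)
  # vanishing reaction rate yields nothing
  slow <- reaction_yields(mk(1e-6), tg)
  expect_lt(tail(slow$reacted_C, 1), 0.01)
  # intermediate regime: tens of percent of competitor reacted although at
  # equilibrium only a few percent of bound probe is C:P
  eq <- equilibrium_accuracy(mk(10))
  expect_gt(eq$theta_eq, 0.95)
  mid <- reaction_yields(mk(10), tg)
  yl <- tail(mid$reacted_C, 1)
  expect_gt(yl, 0.1); expect_lt(yl, 0.6)
  # competitor yield is nondecreasing and plateaus
  expect_true(all(diff(mid$reacted_C) > -1e-12))
  expect_error(reaction_yields(mixture_system(2e-7, 2e-7, 2e-7, 1e7, 1e-5,
                                              8e6, 1e-3), tg),
               "reaction channel")
})
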