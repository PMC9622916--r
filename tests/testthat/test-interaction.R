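test_that("RERI arithmetic on known relative risks is exact", {
  # exact additivity: rr11 = rr10 + rr01 - 1
  est0 <- reri_binary(fake_joint_fit(log(1.2), log(1.3), log(1.5)))
  expect_equal(est0$reri, 0, tolerance = 1e-12)

  est <- reri_binary(fake_joint_fit(log(1.2), log(1.3), log(2.0)))
  expect_equal(est$rr10, 1.2)
  expect_equal(est$rr01, 1.3)
  expect_equal(est$rr11, 2.0)
  expect_equal(est$reri, 0.5, tolerance = 1e-12)
  # structural invariants
  expect_equal(est$reri, est$rr11 - est$rr10 - est$rr01 + 1)
  expect_true(est$ci95[1] <= est$reri && est$reri <= est$ci95[2])
  expect_true(est$p_additive >= 0 && est$p_additive <= 1)
})

test_that("RERI is symmetric under swapping the two exposures", {
  vc <- matrix(c(4, 1, 2, 1, 5, 1.5, 2, 1.5, 7) * 1e-3, 3, 3)
  f1 <- fake_joint_fit(log(1.4), log(1.7), log(2.4), vc)
  # swap BP-only and score-only roles (permute coefficients and covariance)
  perm <- c(2, 1, 3)
  f2 <- fake_joint_fit(log(1.7), log(1.4), log(2.4), vc[perm, perm])
  e1 <- reri_binary(f1)
  e2 <- reri_binary(f2)
  expect_equal(e1$reri, e2$reri)
  expect_equal(e1$se, e2$se)
})

test_that("zero product coefficient implies RERI = (RR10-1)(RR01-1)", {
  for (b in list(c(0.2, 0.35), c(0.05, 0.6), c(0.4, 0.4))) {
    est <- reri_binary(fake_joint_fit(b[1], b[2], b[1] + b[2]))
    expect_equal(est$reri, (exp(b[1]) - 1) * (exp(b[2]) - 1),
                 tolerance = 1e-12)
    expect_gte(est$reri, 0)
  }
})

test_that("continuous-scale RERI matches the plug-in oracle and its gradient", {
  # beta chosen so the implied joint RRs are (1.2, 1.3, 2.0) at delta = 1
  b <- c(log(1.2), log(1.3), log(2.0 / (1.2 * 1.3)))
  S <- diag(1e-4, 3)
  est <- bpgrs:::reri_delta_continuous(b, S, c(1, 1))
  expect_equal(est$reri, 0.5, tolerance = 1e-12)
  expect_equal(est$rr11, 2.0, tolerance = 1e-12)

  # delta-method gradient against central finite differences
  S2 <- matrix(c(4, 1, 2, 1, 5, 1.5, 2, 1.5, 7) * 1e-3, 3, 3)
  delta <- c(1.5, 0.8)
  reri_of <- function(bb) bpgrs:::reri_delta_continuous(bb, S2, delta)$reri
  h <- 1e-6
  g_num <- vapply(1:3, function(j) {
    e <- rep(0, 3); e[j] <- h
    (reri_of(b + e) - reri_of(b - e)) / (2 * h)
  }, numeric(1))
  est2 <- bpgrs:::reri_delta_continuous(b, S2, delta)
  se_num <- sqrt(as.numeric(t(g_num) %*% S2 %*% g_num))
  expect_equal(est2$se, se_num, tolerance = 1e-6)

  # beta3 = 0 with zero main effects: RERI identically 0 for any delta
  expect_equal(bpgrs:::reri_delta_continuous(c(0, 0, 0), S, c(2, 0.5))$reri, 0)
})

test_that("full interaction analysis recovers an injected additive interaction", {
  sim <- simulate_cohort(quick_cfg(
    n = 20000, seed = 47,
    joint_rr = list(outcome = "uc_aggressive",
                    rr10 = 1.2, rr01 = 1.3, rr11 = 2.0)))
  est <- reri_analysis(sim$cohort, "uc_aggressive", "sbp",
                       adjust = character(0))
  truth <- 2.0 - 1.2 - 1.3 + 1
  expect_lt(abs(est$reri - truth), 3 * est$se)
  expect_true(est$p_multiplicative >= 0 && est$p_multiplicative <= 1)
  # four-group HR table with reference 1
  expect_equal(est$group_hr$estimate[est$group_hr$group == "ref"], 1)
  expect_equal(nrow(est$group_hr), 4)
})

test_that("reri_continuous validates increments and runs on simulated data", {
  sim <- simulate_cohort(quick_cfg(n = 8000, seed = 53))
  expect_error(reri_continuous(sim$cohort, "uc_aggressive", "sbp",
                               character(0), delta = c(-1, 1)),
               "delta")
  est <- reri_continuous(sim$cohort, "uc_aggressive", "sbp", character(0))
  expect_s3_class(est, "reri_estimate")
  expect_identical(est$scale, "continuous")
  # the +-2 SD restriction drops the tails
  expect_lt(est$fit$n, 8000)
  expect_gt(est$fit$n, 0.9 * 8000)
})

test_that("sensitivity analysis reproduces the single-cut result exactly", {
  sim <- simulate_cohort(quick_cfg(n = 15000, seed = 59,
                                   joint_rr = list(outcome = "uc_aggressive",
                                                   rr10 = 1.2, rr01 = 1.3,
                                                   rr11 = 2.0)))
  co <- sim$cohort
  tab <- sensitivity_cuts(co, "uc_aggressive", "sbp", cuts = 140,
                          adjust = character(0))
  single <- tidy(reri_analysis(co, "uc_aggressive", "sbp", 140,
                               adjust = character(0)))
  expect_equal(tab$estimate, single$estimate)
  expect_equal(tab$std.error, single$std.error)

  expect_error(sensitivity_cuts(co, "uc_aggressive", "sbp", cuts = 20,
                                adjust = character(0)),
               "outside the observed")
})

test_that("estimates attenuate off the generating threshold on average", {
  reps <- purrr::map_dfr(1:25, function(i) {
    sim <- simulate_cohort(quick_cfg(
      n = 8000, seed = 600 + i,
      joint_rr = list(outcome = "uc_aggressive",
                      rr10 = 1.5, rr01 = 1.5, rr11 = 3.0)))
    sensitivity_cuts(sim$cohort, "uc_aggressive", "sbp",
                     cuts = c(130, 140, 150), adjust = character(0))[,
                       c("bp_cut", "estimate")]
  })
  m <- tapply(reps$estimate, reps$bp_cut, mean)
  expect_gt(m[["140"]], m[["130"]])
  expect_gt(m[["140"]], m[["150"]])
})

test_that("reri_binary demands the joint-group terms and a usable covariance", {
  sim <- simulate_cohort(quick_cfg(n = 5000, seed = 61))
  fit <- fit_cox(sim$cohort, "sbp_z", "uc_aggressive", character(0))
  expect_error(reri_binary(fit), "joint-group term")

  f <- fake_joint_fit(0.1, 0.2, 0.4, matrix(0, 3, 3))
  expect_error(reri_binary(f), "singular")
})
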