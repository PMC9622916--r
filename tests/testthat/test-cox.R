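# deterministic toy cohort: 6 men, delayed entry, untied event ages
toy6 <- tibble::tibble(
  id = sprintf("p%d", 1:6),
  entry_age = c(50, 52, 55, 51, 58, 60),
  exit_age = c(59.5, 70.2, 66.1, 58.3, 72.8, 65.4),
  event = factor(c("uc_aggressive", "censored", "uc_aggressive", "death",
                   "uc_aggressive", "censored"),
                 levels = c("censored", "uc_nonaggressive", "uc_aggressive",
                            "death")),
  x = c(0.2, 1.0, -0.5, 0.1, 0.7, -1.2)
)

test_that("partial likelihood equals brute-force risk-set enumeration", {
  fit <- fit_cox(toy6, "x", "uc_aggressive", adjust = character(0))
  status <- as.integer(toy6$event == "uc_aggressive")
  X <- matrix(toy6$x, ncol = 1)
  # at the MLE and at zero (no ties, so Efron = Breslow = exact)
  expect_equal(fit$loglik[["model"]],
               bf_cox_loglik(toy6$entry_age, toy6$exit_age, status, X,
                             fit$coefficients),
               tolerance = 1e-10)
  expect_equal(fit$loglik[["null"]],
               bf_cox_loglik(toy6$entry_age, toy6$exit_age, status, X, 0),
               tolerance = 1e-12)
  # delayed entry matters: p6 (entry 60) is outside the risk set of the
  # age-59.5 event; pretending everyone was at risk from birth changes
  # the likelihood
  expect_false(isTRUE(all.equal(
    fit$loglik[["null"]],
    bf_cox_loglik(rep(0, 6), toy6$exit_age, status, X, 0))))
})

test_that("two mirror-image exposure groups give a zero coefficient", {
  mirror <- tibble::tibble(
    entry_age = rep(c(50, 53, 56), 2),
    exit_age = rep(c(60.1, 63.7, 67.3), 2),
    event = factor(rep(c("uc_aggressive", "censored", "uc_aggressive"), 2),
                   levels = levels(toy6$event)),
    x = rep(c(0, 1), each = 3)
  )
  fit <- fit_cox(mirror, "x", "uc_aggressive", adjust = character(0))
  expect_equal(unname(fit$coefficients["x"]), 0, tolerance = 1e-8)
})

test_that("cause-specific event counts add up across outcomes", {
  sim <- simulate_cohort(quick_cfg(n = 4000, seed = 17))
  co <- sim$cohort
  f_tot <- fit_cox(co, exposure_spec("sbp", "per_sd"), "uc_total",
                   character(0))
  f_na <- fit_cox(co, exposure_spec("sbp", "per_sd"), "uc_nonaggressive",
                  character(0))
  f_ag <- fit_cox(co, exposure_spec("sbp", "per_sd"), "uc_aggressive",
                  character(0))
  expect_equal(f_tot$n_events, f_na$n_events + f_ag$n_events)
  expect_equal(f_tot$n, f_na$n)
  # adding a term can only raise the partial likelihood
  f2 <- fit_cox(co, c("sbp_z", "wgrs_z"), "uc_aggressive", character(0))
  f1 <- fit_cox(co, "sbp_z", "uc_aggressive", character(0))
  expect_gte(f2$loglik[["model"]], f1$loglik[["model"]] - 1e-10)
  expect_identical(class(lr_test(f1, f2)), class(tibble::tibble()))
})

test_that("per-SD hazard ratio recovers an injected effect", {
  eff <- list(uc_nonaggressive = NULL,
              uc_aggressive = c(sbp_z = 0.25), death = NULL)
  sim <- simulate_cohort(quick_cfg(n = 30000, seed = 19, effects = eff))
  fit <- fit_cox(sim$cohort, exposure_spec("sbp", "per_sd"),
                 "uc_aggressive", character(0))
  b <- fit$coefficients["sbp_per_sd"]
  se <- sqrt(diag(fit$vcov))["sbp_per_sd"]
  expect_lt(abs(b - 0.25), 3 * se)
})

test_that("trend test needs >= 3 categories and flags a strong gradient", {
  sim <- simulate_cohort(quick_cfg(n = 8000, seed = 23,
                                   effects = list(uc_aggressive =
                                                    c(sbp_z = 0.5))))
  tt <- trend_test(sim$cohort, exposure_spec("sbp", "categorical"),
                   "uc_aggressive", character(0))
  expect_equal(tt$n_categories, 4)
  expect_lt(tt$p.value, 0.01)
  expect_gt(tt$estimate, 0)

  expect_error(trend_test(sim$cohort,
                          exposure_spec("sbp", "categorical", breaks = 140),
                          "uc_aggressive", character(0)),
               ">= 3")
})

test_that("Schoenfeld diagnostics behave at the MLE and detect gross violation", {
  sim <- simulate_cohort(quick_cfg(n = 5000, seed = 29))
  fit <- fit_cox(sim$cohort, exposure_spec("sbp", "per_sd"), "uc_aggressive",
                 character(0))
  # score equation: Schoenfeld residuals sum to ~0 per term
  res <- residuals(fit$model, type = "schoenfeld")
  expect_lt(max(abs(sum(res))), 1e-8)

  ph <- ph_check(fit)
  expect_identical(ph$term[nrow(ph)], "GLOBAL")
  expect_true(all(ph$p.value >= 0 & ph$p.value <= 1))
  # proportional data at a frozen seed: no violation signal
  expect_gt(ph$p.value[1], 0.01)

  # gross non-proportionality: hazards cross at age 60 (exposed high
  # early / low late, unexposed the reverse)
  set.seed(71)
  n_g <- 1000
  two_period <- function(h_early, h_late) {
    t1 <- rexp(n_g, h_early)
    ifelse(t1 < 10, t1, 10 + rexp(n_g, h_late))
  }
  np <- tibble::tibble(
    entry_age = rep(50, 2 * n_g),
    exit_age = 50 + pmin(c(two_period(0.15, 0.01),
                           two_period(0.01, 0.15)), 20),
    x = rep(c(1, 0), each = n_g))
  np$event <- factor(ifelse(np$exit_age < 70, "uc_aggressive", "censored"),
                     levels = levels(toy6$event))
  np$exit_age <- np$exit_age + runif(2 * n_g, 0, 1e-6) # break exact ties
  np_fit <- fit_cox(np, "x", "uc_aggressive", character(0))
  expect_lt(ph_check(np_fit)$p.value[1], 0.01)
})

test_that("fit errors are explicit: no events, missing columns, nesting", {
  expect_error(fit_cox(toy6, "x", "uc_nonaggressive", character(0)),
               "no events")
  expect_error(fit_cox(toy6, "nope", "uc_aggressive", character(0)),
               "lacks column")
  f1 <- fit_cox(toy6, "x", "uc_aggressive", character(0))
  expect_error(lr_test(f1, fit_cox(toy6[-6, ], "x", "uc_aggressive",
                                   character(0))),
               "different analysis samples")
  # identical term sets: degenerate comparison, stat 0 and p 1
  same <- lr_test(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("an event-free adjustment category warns instead of failing", {
  co <- simulate_cohort(quick_cfg(n = 2000, seed = 97))$cohort
  co$flag <- factor(ifelse(co$event == "censored" & seq_len(2000) <= 250,
                           "rare", "common"),
                    levels = c("common", "rare"))
  w <- capture_warnings(fit <- fit_cox(co, "sbp_z", "uc_aggressive",
                                       adjust = "flag"))
  expect_true(any(grepl("not estimable", w)))
  # the exposure coefficient stays valid
  expect_true(is.finite(fit$coefficients["sbp_z"]))
})

test_that("complete-case filtering drops covariate-missing rows per model", {
  sim <- simulate_cohort(sim_config(n = 2000, seed = 37,
                                    n_genotype_missing = 50L,
                                    n_bmi_missing = 20L,
                                    n_education_missing = 10L))
  co <- sim$cohort
  fit <- fit_cox(co, exposure_spec("sbp", "per_sd"), "uc_total",
                 adjust = c("smoking", "bmi_quartile", "education"))
  expect_equal(fit$n,
               sum(stats::complete.cases(co[, c("sbp", "bmi_quartile",
                                                "education")])))
})
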