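ev_levels <- c("censored", "uc_nonaggressive", "uc_aggressive", "death")

# hazard table with constant rates over an age span, built directly
const_hazards <- function(h1, h2, from = 60, to = 80, by = 1) {
  s <- seq(from, to - by, by = by)
  tibble::tibble(age_start = s, age_end = s + by,
                 person_years = 1000, n_event = NA, n_death = NA,
                 rate_event = h1, rate_death = h2)
}

test_that("single-person band bookkeeping is exact", {
  co <- tibble::tibble(entry_age = 60, exit_age = 62,
                       event = factor("uc_aggressive", levels = ev_levels))
  hz <- estimate_hazards(co, "uc_aggressive")
  expect_equal(hz$person_years, c(1, 1))
  expect_equal(hz$n_event, c(0, 1))  # event at 62 closes the (61, 62] band
  expect_equal(hz$rate_event, c(0, 1))

  bad <- tibble::tibble(entry_age = 62, exit_age = 60,
                        event = factor("death", levels = ev_levels))
  expect_error(estimate_hazards(bad), "exceed entry_age")
})

test_that("estimated band rates recover a constant hazard within 3 SE", {
  h <- 0.01
  cfg <- sim_config(n = 50000, seed = 71, genotypes = FALSE,
                    n_bmi_missing = 0L, n_education_missing = 0L,
                    admin_censor_years = 15, effects = list(),
                    hazard = list(uc_nonaggressive = list(rate60 = h, slope = 0),
                                  uc_aggressive = list(rate60 = 0, slope = 0),
                                  death = list(rate60 = 0, slope = 0)))
  sim <- simulate_cohort(cfg)
  hz <- suppressMessages(estimate_hazards(sim$cohort, "uc_nonaggressive"))
  busy <- hz[hz$person_years > 5000, ]
  # Poisson SE per band: sqrt(expected events) / person-years
  expect_true(all(abs(busy$rate_event - h) <=
                    3 * sqrt(h * busy$person_years) / busy$person_years))
})

test_that("absolute risk matches constant-hazard closed forms", {
  # no competing mortality: risk = 1 - exp(-h1 * t)
  a1 <- absolute_risk(const_hazards(0.001, 0), 60, 20)
  expect_equal(a1$risk, 1 - exp(-0.02), tolerance = 1e-12)

  # with competing death: risk = h1/(h1+h2) * (1 - exp(-(h1+h2) t))
  a2 <- absolute_risk(const_hazards(0.001, 0.02), 60, 20)
  expect_equal(a2$risk, (0.001 / 0.021) * (1 - exp(-0.021 * 20)),
               tolerance = 1e-12)
  expect_lt(abs(a2$risk - 0.016331), 1e-6)

  # all rates zero
  expect_equal(absolute_risk(const_hazards(0, 0), 60, 20)$risk, 0)

  # risk is non-decreasing in the horizon
  r10 <- absolute_risk(const_hazards(0.001, 0.02), 60, 10)$risk
  expect_gte(a2$risk, r10)

  expect_error(absolute_risk(const_hazards(0.001, 0.02, 60, 70), 60, 20),
               "cover")
  neg <- const_hazards(0.001, 0.02)
  neg$rate_event[3] <- -1e-6
  expect_error(absolute_risk(neg, 60, 20), "negative")
})

test_that("two-cause decomposition sums to one within 1e-12", {
  set.seed(77)
  for (i in 1:5) {
    hz <- const_hazards(0, 0)
    hz$rate_event <- runif(nrow(hz), 0, 0.05)
    hz$rate_death <- runif(nrow(hz), 0, 0.1)
    a <- absolute_risk(hz, 60, 20)
    expect_equal(a$risk + a$risk_competing + a$event_free, 1,
                 tolerance = 1e-12)
    # swapping the two causes swaps the two risks exactly
    sw <- hz
    sw$rate_event <- hz$rate_death
    sw$rate_death <- hz$rate_event
    expect_equal(absolute_risk(sw, 60, 20)$risk, a$risk_competing,
                 tolerance = 1e-14)
  }
})

test_that("band refinement changes a smooth-hazard risk by < 1e-3", {
  h1_fun <- function(a) 0.002 * exp(0.06 * (a - 60))
  h2_fun <- function(a) 0.01 * exp(0.09 * (a - 60))
  mk <- function(by) {
    s <- seq(60, 80 - by, by = by)
    tibble::tibble(age_start = s, age_end = s + by, person_years = 1,
                   n_event = NA, n_death = NA,
                   rate_event = h1_fun(s + by / 2),
                   rate_death = h2_fun(s + by / 2))
  }
  r_year <- absolute_risk(mk(1), 60, 20)$risk
  r_month <- absolute_risk(mk(1 / 12), 60, 20)$risk
  expect_lt(abs(r_year - r_month), 1e-3)
})

test_that("rates (and hence risks) are invariant to cohort duplication", {
  sim <- simulate_cohort(quick_cfg(n = 3000, seed = 83))
  co <- sim$cohort
  doubled <- dplyr::bind_rows(co, co)
  b <- seq(60, 80, 1)
  h1 <- suppressMessages(estimate_hazards(co, "uc_total", b))
  h2 <- suppressMessages(estimate_hazards(doubled, "uc_total", b))
  expect_equal(h2$person_years, 2 * h1$person_years)
  expect_equal(h2$rate_event, h1$rate_event)
  expect_equal(absolute_risk(h2, 60, 20)$risk,
               absolute_risk(h1, 60, 20)$risk)
})

test_that("group absolute risks reflect an injected hazard ratio", {
  sim <- simulate_cohort(quick_cfg(
    n = 40000, seed = 89,
    joint_rr = list(outcome = "uc_aggressive",
                    rr10 = 1, rr01 = 1, rr11 = 2)))
  co <- add_joint_groups(sim$cohort, "sbp")
  risks <- group_absolute_risks(co, "uc_aggressive", 60, 20,
                                shared_death = TRUE)
  expect_equal(nrow(risks), 4)
  r_ref <- risks$risk[risks$group == "ref"]
  r_both <- risks$risk[risks$group == "both"]
  # rare-event approximation: risk ratio ~ hazard ratio 2
  expect_gt(r_both / r_ref, 1.4)
  expect_lt(r_both / r_ref, 2.7)
  # horizon monotonicity per group
  risks10 <- group_absolute_risks(co, "uc_aggressive", 60, 10,
                                  shared_death = TRUE)
  expect_true(all(risks$risk >= risks10$risk - 1e-12))

  tiny <- co[co$entry_age > 72.9, ]
  expect_error(group_absolute_risks(tiny, "uc_aggressive", 40, 5),
               "person-years")
})
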