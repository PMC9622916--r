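#' Estimate cause-specific hazards on an age-band grid
#'
#' Occurrence/exposure rates per age band: person-years are the overlap of
#' each person's at-risk interval `(entry_age, exit_age]` with the band, and
#' events are counted in the band containing `exit_age` (bands are treated
#' as half-open `(a, a+1]` so an exit exactly on a boundary falls in the
#' band it closes). The band rate for the outcome and for competing death is
#' `events / person-years`; bands with no exposure get rate 0 with a logged
#' warning.
#'
#' @param cohort Cohort tibble with `entry_age`, `exit_age`, `event`.
#' @param outcome `"uc_total"`, `"uc_nonaggressive"` or `"uc_aggressive"`
#'   (the competing cause is always death).
#' @param breaks Age-grid break points; default: 1-year bands spanning the
#'   observed ages.
#' @return A `hazard_table` tibble: `age_start`, `age_end`, `person_years`,
#'   `n_event`, `n_death`, `rate_event`, `rate_death`.
#' @export
estimate_hazards <- function(cohort, outcome = "uc_total", breaks = NULL) {
  if (any(cohort$exit_age <= cohort$entry_age)) {
    abort("exit_age must exceed entry_age for every person")
  }
  ev <- outcome_events(outcome)
  if (is.null(breaks)) {
    breaks <- seq(floor(min(cohort$entry_age)),
                  ceiling(max(cohort$exit_age)), by = 1)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be strictly increasing")
  }
  nb <- length(breaks) - 1
  s <- breaks[-length(breaks)]
  e <- breaks[-1]
  py <- vapply(seq_len(nb), function(j) {
    sum(pmax(0, pmin(cohort$exit_age, e[j]) - pmax(cohort$entry_age, s[j])))
  }, numeric(1))
  band_of_exit <- findInterval(cohort$exit_age, breaks, left.open = TRUE)
  in_grid <- band_of_exit >= 1 & band_of_exit <= nb
  is_event <- cohort$event %in% ev & in_grid
  is_death <- cohort$event == "death" & in_grid
  n_event <- tabulate(band_of_exit[is_event], nbins = nb)
  n_death <- tabulate(band_of_exit[is_death], nbins = nb)
  if (any(py == 0 & (n_event > 0 | n_death > 0))) {
    abort("events recorded in a band with zero person-years")
  }
  empty <- py == 0
  if (any(empty)) {
    inform(paste0(sum(empty), " age band(s) carry no person-years; ",
                  "their rates are set to 0"))
  }
  rate <- function(n) ifelse(py > 0, n / py, 0)
  structure(tibble::tibble(
    age_start = s, age_end = e, person_years = py,
    n_event = n_event, n_death = n_death,
    rate_event = rate(n_event), rate_death = rate(n_death)
  ), class = c("hazard_table", "tbl_df", "tbl", "data.frame"),
  outcome = outcome)
}

#' Absolute risk over a horizon with death as a competing event
#'
#' Piecewise-exponential cause-specific integration: with outcome hazard
#' \eqn{h_{1j}} and death hazard \eqn{h_{2j}} constant on band *j* of width
#' \eqn{w_j},
#' \deqn{risk = \sum_j S_{j-1} \frac{h_{1j}}{h_{1j}+h_{2j}}
#'   \left(1 - e^{-(h_{1j}+h_{2j}) w_j}\right),}
#' where \eqn{S_{j-1}} is the probability of being event-free at the start
#' of band *j*. A band with both hazards zero contributes nothing. The
#' competing-death risk and the event-free probability are returned
#' alongside; the three sum to 1 by construction of the decomposition.
#'
#' @param hazards A `hazard_table` from [estimate_hazards()].
#' @param start_age Age at which the risk window opens (years).
#' @param horizon Window length (years, default 20).
#' @return One-row tibble: `start_age`, `horizon`, `risk`,
#'   `risk_competing`, `event_free`.
#' @export
absolute_risk <- function(hazards, start_age = 60, horizon = 20) {
  if (horizon <= 0) abort("horizon must be positive")
  if (any(hazards$rate_event < 0) || any(hazards$rate_death < 0)) {
    abort("negative hazard rate")
  }
  end_age <- start_age + horizon
  if (start_age < min(hazards$age_start) - 1e-9 ||
      end_age > max(hazards$age_end) + 1e-9) {
    abort("hazard bands do not cover the requested risk window")
  }
  h <- hazards[hazards$age_end > start_age & hazards$age_start < end_age, ]
  w <- pmin(h$age_end, end_age) - pmax(h$age_start, start_age)
  h1 <- h$rate_event
  h2 <- h$rate_death
  htot <- h1 + h2
  surv_band <- exp(-htot * w)
  surv_start <- cumprod(c(1, surv_band[-length(surv_band)]))
  frac <- function(hk) ifelse(htot > 0, hk / htot, 0)
  risk1 <- sum(surv_start * frac(h1) * (1 - surv_band))
  risk2 <- sum(surv_start * frac(h2) * (1 - surv_band))
  tibble::tibble(start_age = start_age, horizon = horizon,
                 risk = risk1, risk_competing = risk2,
                 event_free = prod(surv_band))
}

#' Absolute risks per joint exposure group
#'
#' Estimates group-specific hazards (outcome and death within each joint
#' BP/score group; optionally a shared death hazard from the whole cohort)
#' on 1-year bands over the risk window, and integrates each to the
#' competing-risk absolute risk.
#'
#' @inheritParams absolute_risk
#' @param cohort Cohort tibble carrying a `joint_group` column (see
#'   [add_joint_groups()]), or the grouping column named by `group_col`.
#' @param outcome Outcome whose risk is integrated.
#' @param group_col Name of the grouping column.
#' @param shared_death Use the whole-cohort death hazard for every group
#'   instead of group-specific death hazards (default `FALSE`: blood
#'   pressure is allowed to affect mortality).
#' @return Tibble: `group`, `start_age`, `horizon`, `risk`, `risk_percent`.
#' @export
group_absolute_risks <- function(cohort, outcome = "uc_total",
                                 start_age = 60, horizon = 20,
                                 group_col = "joint_group",
                                 shared_death = FALSE) {
  if (!group_col %in% names(cohort)) {
    abort(paste0("cohort lacks grouping column ", group_col))
  }
  breaks <- seq(floor(start_age), ceiling(start_age + horizon), by = 1)
  grp <- cohort[[group_col]]
  shared <- if (shared_death) {
    suppressMessages(estimate_hazards(cohort, outcome, breaks))
  } else NULL
  purrr::map_dfr(levels(factor(grp)), function(g) {
    sub <- cohort[!is.na(grp) & grp == g, ]
    hz <- suppressMessages(estimate_hazards(sub, outcome, breaks))
    if (sum(hz$person_years) == 0) {
      abort(paste0("group ", g, " has no person-years in the risk window"))
    }
    if (shared_death) hz$rate_death <- shared$rate_death
    ar <- absolute_risk(hz, start_age, horizon)
    tibble::tibble(group = g, start_age = start_age, horizon = horizon,
                   risk = ar$risk, risk_percent = 100 * ar$risk)
  })
}
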