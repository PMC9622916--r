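#' Partition a cohort into joint blood-pressure / genetic-risk groups
#'
#' The reference group combines normal blood pressure (below `bp_cut`) with
#' the lower half of the genetic risk score; the other three groups carry
#' high BP only, high score only, or both. The score split is the sample
#' median: the `median_group` column is used when present (so a split fixed
#' upstream stays fixed across BP sensitivity cuts), otherwise `raw_score`
#' is split at its median.
#'
#' @param cohort Cohort tibble.
#' @param bp_var `"sbp"` or `"dbp"`.
#' @param bp_cut Threshold defining high BP (mmHg); default 140 for SBP,
#'   90 for DBP.
#' @return `cohort` with logical `bp_high`, `grs_high` and factor
#'   `joint_group` (levels `ref`, `bp_only`, `grs_only`, `both`) appended.
#'   Errors if any joint group is empty.
#' @export
add_joint_groups <- function(cohort, bp_var = c("sbp", "dbp"), bp_cut = NULL) {
  bp_var <- match.arg(bp_var)
  bp_cut <- bp_cut %||% (if (bp_var == "sbp") 140 else 90)
  bp <- cohort[[bp_var]]
  if (bp_cut <= min(bp, na.rm = TRUE) || bp_cut > max(bp, na.rm = TRUE)) {
    abort(paste0("BP cut ", bp_cut, " outside the observed ", bp_var,
                 " range"))
  }
  cohort$bp_high <- bp >= bp_cut
  if ("median_group" %in% names(cohort)) {
    cohort$grs_high <- cohort$median_group == "upper50"
  } else if ("raw_score" %in% names(cohort)) {
    cohort$grs_high <- cohort$raw_score > median(cohort$raw_score, na.rm = TRUE)
  } else {
    abort("cohort needs a median_group or raw_score column for the score split")
  }
  g <- dplyr::case_when(
    cohort$bp_high & cohort$grs_high ~ "both",
    cohort$bp_high ~ "bp_only",
    cohort$grs_high ~ "grs_only",
    !is.na(cohort$bp_high) & !is.na(cohort$grs_high) ~ "ref")
  cohort$joint_group <- factor(g, levels = c("ref", "bp_only", "grs_only",
                                             "both"))
  tab <- table(cohort$joint_group)
  if (any(tab == 0)) {
    abort(paste0("empty joint exposure group(s): ",
                 paste(names(tab)[tab == 0], collapse = ", ")))
  }
  cohort
}

new_reri_estimate <- function(rr10, rr01, rr11, reri, se, p_additive,
                              scale, extra = list()) {
  ci <- reri + c(-1, 1) * qnorm(0.975) * se
  structure(c(list(rr10 = rr10, rr01 = rr01, rr11 = rr11, reri = reri,
                   se = se, ci95 = ci, p_additive = p_additive,
                   p_multiplicative = NA_real_, scale = scale), extra),
            class = "reri_estimate")
}

#' Relative excess risk due to interaction from a joint-group Cox fit
#'
#' For a fit with the three joint-group indicators (reference omitted),
#' computes `RERI = RR11 - RR10 - RR01 + 1` with the Hosmer–Lemeshow
#' delta-method variance on the relative-risk scale: gradient
#' `(-RR10, -RR01, RR11)` over the `(b10, b01, b11)` sub-covariance, a
#' symmetric 95% Wald interval, and a two-sided Wald p-value from
#' `RERI / SE`. RERI > 0 indicates super-additive joint effects.
#'
#' @param fit A `bpgrs_cox` fit whose exposure is the `joint_group` factor
#'   from [add_joint_groups()], or whose coefficient names are supplied via
#'   `terms`.
#' @param terms Optional character vector naming, in order, the coefficients
#'   for (BP only, score only, both).
#' @return A `reri_estimate` object.
#' @export
reri_binary <- function(fit, terms = NULL) {
  if (is.null(terms)) {
    terms <- paste0("joint_group", c("bp_only", "grs_only", "both"))
  }
  miss <- setdiff(terms, names(fit$coefficients))
  if (length(miss) > 0) {
    abort(paste0("fit lacks joint-group term(s): ",
                 paste(miss, collapse = ", ")))
  }
  b <- fit$coefficients[terms]
  S <- fit$vcov[terms, terms]
  if (any(!is.finite(S)) || det(S) <= 0) {
    abort("singular covariance for the joint-group terms")
  }
  rr <- exp(b)
  reri <- rr[3] - rr[1] - rr[2] + 1
  g <- c(-rr[1], -rr[2], rr[3])
  v <- as.numeric(t(g) %*% S %*% g)
  se <- sqrt(v)
  p <- 2 * pnorm(-abs(reri / se))
  new_reri_estimate(unname(rr[1]), unname(rr[2]), unname(rr[3]),
                    unname(reri), se, unname(p), scale = "binary")
}

#' Full additive + multiplicative interaction analysis for one outcome
#'
#' Builds the four joint BP/score groups, fits the adjusted cause-specific
#' Cox model on the joint-group factor (additive interaction via
#' [reri_binary()]), and tests multiplicative interaction by the
#' likelihood-ratio test of the main-effects model nested in the model with
#' the BP-by-score product term.
#'
#' @inheritParams fit_cox
#' @inheritParams add_joint_groups
#' @return A `reri_estimate` with `p_multiplicative` filled in and the
#'   joint-group hazard-ratio table attached as `$group_hr`.
#' @export
reri_analysis <- function(cohort, outcome = "uc_aggressive",
                          bp_var = c("sbp", "dbp"), bp_cut = NULL,
                          adjust = c("smoking", "bmi_quartile", "activity",
                                     "education")) {
  bp_var <- match.arg(bp_var)
  cohort <- add_joint_groups(cohort, bp_var, bp_cut)
  joint_fit <- fit_cox(cohort, "joint_group", outcome, adjust)
  est <- reri_binary(joint_fit)

  restricted <- fit_cox(cohort, c("bp_high", "grs_high"), outcome, adjust)
  full <- fit_cox(cohort, c("bp_high", "grs_high", "bp_high:grs_high"),
                  outcome, adjust)
  lr <- lr_test(restricted, full)
  est$p_multiplicative <- lr$p.value
  est$lr <- lr

  gh <- tidy.bpgrs_cox(joint_fit, exponentiate = TRUE)
  gh <- gh[startsWith(gh$term, "joint_group"), ]
  est$group_hr <- dplyr::bind_rows(
    tibble::tibble(term = "joint_groupref", estimate = 1,
                   std.error = NA, statistic = NA, p.value = NA,
                   conf.low = NA, conf.high = NA), gh) |>
    dplyr::mutate(group = sub("^joint_group", "", .data$term),
                  .before = 1) |>
    dplyr::select(-"term")
  est$outcome <- outcome
  est$bp_var <- bp_var
  est$bp_cut <- bp_cut %||% (if (bp_var == "sbp") 140 else 90)
  est$fit <- joint_fit
  est
}

#' Additive interaction on the continuous (z-score) scale
#'
#' Both exposures are z-scored on the analysis sample, the sample is
#' restricted jointly to observations within ± `sd_limit` SD of both, and a
#' Cox model with main effects and their product is fitted. For increments
#' `delta = (d1, d2)` from the mean,
#' \deqn{RERI = e^{\beta_1 d_1 + \beta_2 d_2 + \beta_3 d_1 d_2}
#'   - e^{\beta_1 d_1} - e^{\beta_2 d_2} + 1,}
#' with delta-method gradient `d1*(R11 - R10)`, `d2*(R11 - R01)`,
#' `d1*d2*R11` over the three-term sub-covariance. The multiplicative LR
#' test on the same restricted sample fills `p_multiplicative`.
#'
#' @inheritParams fit_cox
#' @param bp_var `"sbp"` or `"dbp"`.
#' @param delta Positive increments (in SD units) at which to evaluate the
#'   interaction; default +1 SD in both exposures.
#' @param sd_limit Joint restriction window in SD units (default 2).
#' @return A `reri_estimate` (scale `"continuous"`).
#' @export
reri_continuous <- function(cohort, outcome = "uc_aggressive",
                            bp_var = c("sbp", "dbp"),
                            adjust = c("smoking", "bmi_quartile", "activity",
                                       "education"),
                            delta = c(1, 1), sd_limit = 2) {
  bp_var <- match.arg(bp_var)
  if (any(delta <= 0)) abort("increments delta must be > 0")
  if (!"raw_score" %in% names(cohort)) {
    abort("cohort needs a raw_score column")
  }
  used <- c("entry_age", "exit_age", "event", bp_var, "raw_score", adjust)
  d <- cohort[stats::complete.cases(cohort[, used]), ]
  d$z1 <- as.numeric(scale(d[[bp_var]]))
  d$z2 <- as.numeric(scale(d$raw_score))
  d <- d[abs(d$z1) <= sd_limit & abs(d$z2) <= sd_limit, ]

  full <- fit_cox(d, c("z1", "z2", "z1:z2"), outcome, adjust)
  restricted <- fit_cox(d, c("z1", "z2"), outcome, adjust)
  lr <- lr_test(restricted, full)

  tm <- c("z1", "z2", "z1:z2")
  est <- reri_delta_continuous(full$coefficients[tm], full$vcov[tm, tm],
                               delta)
  est$sd_limit <- sd_limit
  est$p_multiplicative <- lr$p.value
  est$lr <- lr
  est$outcome <- outcome
  est$bp_var <- bp_var
  est$fit <- full
  est
}

## continuous-scale RERI and delta-method variance from the three model
## coefficients (main1, main2, product) and their covariance, evaluated at
## increments delta = (d1, d2) from the mean
reri_delta_continuous <- function(b, S, delta) {
  d1 <- delta[1]
  d2 <- delta[2]
  r11 <- exp(b[1] * d1 + b[2] * d2 + b[3] * d1 * d2)
  r10 <- exp(b[1] * d1)
  r01 <- exp(b[2] * d2)
  reri <- r11 - r10 - r01 + 1
  g <- c(d1 * (r11 - r10), d2 * (r11 - r01), d1 * d2 * r11)
  se <- sqrt(as.numeric(t(g) %*% S %*% g))
  p <- 2 * pnorm(-abs(reri / se))
  new_reri_estimate(unname(r10), unname(r01), unname(r11), unname(reri),
                    se, unname(p), scale = "continuous",
                    extra = list(delta = delta))
}

#' Repeat the additive-interaction analysis over BP thresholds
#'
#' Runs the full joint-group analysis at each systolic cut point, keeping
#' the median score split fixed (taken from the cohort's `median_group`
#' column), and stacks the tidied estimates.
#'
#' @inheritParams reri_analysis
#' @param cuts BP thresholds (mmHg) to try, e.g. `c(130, 140, 150)`.
#' @return Tibble of tidied `reri_estimate` rows with a `bp_cut` column.
#' @export
sensitivity_cuts <- function(cohort, outcome = "uc_aggressive",
                             bp_var = c("sbp", "dbp"),
                             cuts = c(130, 140, 150),
                             adjust = c("smoking", "bmi_quartile", "activity",
                                        "education")) {
  bp_var <- match.arg(bp_var)
  purrr::map_dfr(cuts, function(ct) {
    est <- reri_analysis(cohort, outcome, bp_var, bp_cut = ct, adjust)
    dplyr::mutate(tidy.reri_estimate(est), bp_cut = ct, .before = 1)
  })
}

#' Tidy a RERI estimate
#'
#' @param x A `reri_estimate`.
#' @param ... Unused.
#' @return One-row tibble: the three relative risks, the RERI point
#'   estimate (`estimate`), its delta-method `std.error`, Wald `conf.low` /
#'   `conf.high`, and the additive and multiplicative interaction p-values.
#' @method tidy reri_estimate
#' @export
tidy.reri_estimate <- function(x, ...) {
  tibble::tibble(scale = x$scale, rr10 = x$rr10, rr01 = x$rr01,
                 rr11 = x$rr11, estimate = x$reri, std.error = x$se,
                 conf.low = x$ci95[1], conf.high = x$ci95[2],
                 p.additive = x$p_additive,
                 p.multiplicative = x$p_multiplicative)
}

#' @export
print.reri_estimate <- function(x, ...) {
  cat("Additive interaction (", x$scale, " scale)\n", sep = "")
  cat(sprintf("  RR10 %.3f  RR01 %.3f  RR11 %.3f\n", x$rr10, x$rr01, x$rr11))
  cat(sprintf("  RERI %.3f (95%% CI %.3f; %.3f), p[add] = %.3g\n",
              x$reri, x$ci95[1], x$ci95[2], x$p_additive))
  if (!is.na(x$p_multiplicative)) {
    cat(sprintf("  p[multiplicative, LR test] = %.3g\n", x$p_multiplicative))
  }
  invisible(x)
}

#' Nonparametric bootstrap of the binary-scale RERI
#'
#' Optional cross-check of the delta-method standard error: resamples
#' individuals with replacement, refits the (unadjusted or adjusted)
#' joint-group model, and returns the replicate RERIs.
#'
#' @inheritParams reri_analysis
#' @param reps Number of bootstrap replicates.
#' @param adjust Adjustment covariates (default none: the bootstrap targets
#'   the delta-method variance, and the unadjusted model keeps it fast).
#' @return Numeric vector of replicate RERI estimates (failed refits are
#'   dropped).
#' @export
reri_bootstrap <- function(cohort, outcome = "uc_aggressive",
                           bp_var = c("sbp", "dbp"), bp_cut = NULL,
                           adjust = character(0), reps = 200) {
  bp_var <- match.arg(bp_var)
  cohort <- add_joint_groups(cohort, bp_var, bp_cut)
  out <- vapply(seq_len(reps), function(i) {
    bs <- cohort[sample.int(nrow(cohort), replace = TRUE), ]
    tryCatch({
      fit <- fit_cox(bs, "joint_group", outcome, adjust)
      reri_binary(fit)$reri
    }, error = function(e) NA_real_)
  }, numeric(1))
  out[is.finite(out)]
}
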