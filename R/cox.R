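#' Specify an exposure for a cause-specific Cox model
#'
#' An exposure enters the model either per standard deviation (`per_sd`;
#' z-scored on the analysis sample after exclusions) or in the conventional
#' clinical categories (`categorical`): SBP `<140, 140–149, 150–159, >=160`
#' mmHg; DBP `<90, 90–94, 95–99, >=100` mmHg; risk score in sample quartiles.
#' The lowest category is always the reference.
#'
#' @param variable `"sbp"`, `"dbp"` or `"wgrs"`.
#' @param form `"per_sd"` or `"categorical"`.
#' @param breaks Interior cut points for the categorical form; defaults to
#'   the clinical cut points above (`NULL` for `wgrs` means sample
#'   quartiles).
#' @return An `exposure_spec` object.
#' @export
exposure_spec <- function(variable = c("sbp", "dbp", "wgrs"),
                          form = c("per_sd", "categorical"),
                          breaks = NULL) {
  variable <- match.arg(variable)
  form <- match.arg(form)
  if (is.null(breaks) && form == "categorical" && variable != "wgrs") {
    breaks <- if (variable == "sbp") c(140, 150, 160) else c(90, 95, 100)
  }
  if (!is.null(breaks) && is.unsorted(breaks, strictly = TRUE)) {
    abort("category breaks must be strictly increasing")
  }
  structure(list(variable = variable, form = form, breaks = breaks),
            class = "exposure_spec")
}

outcome_events <- function(outcome) {
  switch(outcome,
         uc_total = c("uc_nonaggressive", "uc_aggressive"),
         uc_nonaggressive = "uc_nonaggressive",
         uc_aggressive = "uc_aggressive",
         death = "death",
         abort(paste0("unknown outcome: ", outcome)))
}

exposure_column <- function(spec) {
  if (spec$variable == "wgrs") "raw_score" else spec$variable
}

## builds the exposure column(s) on the analysis sample; returns list of
## (data, term) where term is the model-formula term label
build_exposure <- function(data, spec) {
  col <- exposure_column(spec)
  if (!col %in% names(data)) {
    abort(paste0("cohort lacks exposure column ", col))
  }
  x <- data[[col]]
  if (spec$form == "per_sd") {
    term <- paste0(spec$variable, "_per_sd")
    data[[term]] <- (x - mean(x)) / sd(x)
  } else {
    term <- paste0(spec$variable, "_cat")
    if (spec$variable == "wgrs" && is.null(spec$breaks)) {
      cuts <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data[[term]] <- factor(paste0(
        "Q", 1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])))
    } else {
      data[[term]] <- cut(x, c(-Inf, spec$breaks, Inf), right = FALSE)
    }
  }
  list(data = data, term = term)
}

#' Fit a cause-specific Cox model on the attained-age time scale
#'
#' Partial-likelihood fit with delayed entry: each person is at risk from
#' `entry_age` to `exit_age`, so the risk set at an event age contains
#' everyone with `entry_age < t <= exit_age`. Competing events are censored
#' at their event age (cause-specific hazards). Ties are handled by the
#' Efron approximation. Rows with missing values in any model variable are
#' dropped (complete-case per model).
#'
#' @param cohort Cohort tibble with `entry_age`, `exit_age`, `event` and the
#'   model variables.
#' @param exposure An [exposure_spec()], or a character vector of model terms
#'   used verbatim (e.g. `"joint_group"` or
#'   `c("bp_high", "grs_high", "bp_high:grs_high")`).
#' @param outcome One of `"uc_total"`, `"uc_nonaggressive"`,
#'   `"uc_aggressive"`, `"death"`.
#' @param adjust Character vector of adjustment covariates (treated as
#'   factors if not numeric); default smoking (5 categories), BMI quartile,
#'   physical activity, education. Use `character(0)` for an unadjusted fit.
#' @return A `bpgrs_cox` object: coefficients, covariance, log-likelihoods
#'   (null and fitted), event count, the underlying [survival::coxph()] fit,
#'   and the analysis sample.
#' @export
fit_cox <- function(cohort, exposure, outcome = "uc_total",
                    adjust = c("smoking", "bmi_quartile", "activity",
                               "education")) {
  ev <- outcome_events(outcome)
  if (is.character(exposure)) {
    terms_exp <- exposure
    vars_exp <- unique(unlist(strsplit(exposure, ":", fixed = TRUE)))
    spec <- NULL
  } else if (inherits(exposure, "exposure_spec")) {
    spec <- exposure
    vars_exp <- exposure_column(spec)
    terms_exp <- NULL # built after complete-case filtering
  } else {
    abort("exposure must be an exposure_spec or character term vector")
  }

  used <- unique(c("entry_age", "exit_age", "event", vars_exp, adjust))
  miss_cols <- setdiff(used, names(cohort))
  if (length(miss_cols) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(miss_cols, collapse = ", ")))
  }
  data <- as.data.frame(cohort[, used])
  data <- data[stats::complete.cases(data), , drop = FALSE]
  if (any(data$exit_age <= data$entry_age)) {
    abort("exit_age must exceed entry_age for every person")
  }
  data$.status <- as.integer(data$event %in% ev)
  if (sum(data$.status) == 0) abort(paste0("no events of outcome ", outcome))

  if (!is.null(spec)) {
    be <- build_exposure(data, spec)
    data <- be$data
    terms_exp <- be$term
  }
  for (a in adjust) if (!is.numeric(data[[a]])) data[[a]] <- factor(data[[a]])

  fml <- as.formula(paste(
    "survival::Surv(entry_age, exit_age, .status) ~",
    paste(c(terms_exp, adjust), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron", x = TRUE,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (any(is.na(coef(fit)))) {
    abort("model could not estimate every term (collinearity or separation)")
  }
  diverged <- !is.finite(coef(fit)) | abs(coef(fit)) > 15
  if (any(diverged)) {
    bad <- names(coef(fit))[diverged]
    is_exposure <- vapply(bad, function(nm) {
      any(vapply(terms_exp, function(t) startsWith(nm, t), logical(1)))
    }, logical(1))
    if (any(is_exposure)) {
      abort(paste0("apparent separation in exposure term(s): ",
                   paste(bad[is_exposure], collapse = ", ")))
    }
    # an adjustment category with no events: its log-HR runs to -Inf but
    # the remaining coefficients are valid limits; keep the fit and warn
    warn(paste0("adjustment term(s) not estimable (no events in category): ",
                paste(bad, collapse = ", ")))
  }
  structure(list(
    coefficients = coef(fit),
    vcov = vcov(fit),
    loglik = c(null = unname(fit$loglik[1]), model = unname(fit$loglik[2])),
    n = fit$n,
    n_events = fit$nevent,
    outcome = outcome,
    exposure = spec,
    exposure_terms = terms_exp,
    model = fit,
    data = data
  ), class = "bpgrs_cox")
}

#' @export
print.bpgrs_cox <- function(x, ...) {
  cat("Cause-specific Cox model (age time scale), outcome:", x$outcome, "\n")
  cat(x$n, "individuals,", x$n_events, "events\n")
  print(tidy.bpgrs_cox(x, exponentiate = TRUE))
  invisible(x)
}

#' Tidy a cause-specific Cox fit
#'
#' @param x A `bpgrs_cox` object.
#' @param exponentiate Report hazard ratios instead of log-HRs?
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy bpgrs_cox
#' @export
tidy.bpgrs_cox <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  b <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- b / se
  q <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    statistic = unname(z), p.value = 2 * pnorm(-abs(z)),
    conf.low = unname(b - q * se), conf.high = unname(b + q * se))
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a cause-specific Cox fit
#'
#' @param x A `bpgrs_cox` object.
#' @param ... Unused.
#' @return One-row tibble: sample size, event count, log-likelihoods, AIC.
#' @method glance bpgrs_cox
#' @export
glance.bpgrs_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik = x$loglik[["model"]],
                 loglik_null = x$loglik[["null"]],
                 AIC = -2 * x$loglik[["model"]] + 2 * length(x$coefficients))
}

#' Wald trend test across ordered exposure categories
#'
#' Recodes the exposure categories as an ordinal 1..k term, refits the model
#' with that single continuous term, and tests its coefficient with a
#' two-sided Wald test.
#'
#' @inheritParams fit_cox
#' @param exposure An [exposure_spec()] with `form = "categorical"`, or any
#'   spec (the categorical form is imposed).
#' @return One-row tibble: `estimate` (log-HR per category step),
#'   `std.error`, `statistic`, `p.value`, `n_categories`.
#' @export
trend_test <- function(cohort, exposure, outcome = "uc_total",
                       adjust = c("smoking", "bmi_quartile", "activity",
                                  "education")) {
  if (!inherits(exposure, "exposure_spec")) {
    abort("trend_test needs an exposure_spec")
  }
  spec <- exposure_spec(exposure$variable, "categorical", exposure$breaks)
  fit <- fit_cox(cohort, spec, outcome, adjust)
  f <- fit$data[[fit$exposure_terms]]
  k <- nlevels(f)
  if (k < 3) abort("trend test needs >= 3 ordered categories")
  fit$data$.trend <- as.integer(f)
  fml <- as.formula(paste(
    "survival::Surv(entry_age, exit_age, .status) ~ .trend",
    if (length(adjust) > 0) paste("+", paste(adjust, collapse = " + ")) else ""))
  tfit <- survival::coxph(fml, data = fit$data, ties = "efron")
  b <- coef(tfit)[".trend"]
  se <- sqrt(diag(vcov(tfit))[".trend"])
  z <- b / se
  tibble::tibble(estimate = unname(b), std.error = unname(se),
                 statistic = unname(z), p.value = 2 * pnorm(-abs(z)),
                 n_categories = k)
}

#' Proportional-hazards diagnostics via scaled Schoenfeld residuals
#'
#' Correlates each term's scaled Schoenfeld residuals with a transform of
#' event age ([survival::cox.zph()]); a small p-value indicates departure
#' from proportional hazards. The analysis pipeline logs violations rather
#' than failing on them.
#'
#' @param fit A `bpgrs_cox` object with at least 2 events.
#' @param transform Event-age transform passed to [survival::cox.zph()].
#' @return Tibble with one row per term plus a `GLOBAL` row: `term`,
#'   `chisq`, `df`, `p.value`.
#' @export
ph_check <- function(fit, transform = "km") {
  if (fit$n_events < 2) abort("proportional-hazards check needs >= 2 events")
  zp <- survival::cox.zph(fit$model, transform = transform)
  tb <- zp$table
  tibble::tibble(term = rownames(tb), chisq = tb[, "chisq"],
                 df = tb[, "df"], p.value = tb[, "p"])
}

#' Hazard-ratio table across exposures and outcomes
#'
#' Runs, for every exposure and outcome requested, the categorical model
#' (HR per category vs the lowest), the per-SD model, and the ordinal trend
#' test, and stacks the results into one tidy table — the tabular form in
#' which such cohort analyses are conventionally reported.
#'
#' @inheritParams fit_cox
#' @param exposures List of exposure variables (`"sbp"`, `"dbp"`, `"wgrs"`).
#' @param outcomes Character vector of outcomes.
#' @return Tibble: `outcome`, `exposure`, `term`, `hr`, `conf.low`,
#'   `conf.high`, `p.value`, `n`, `n_events` (trend rows carry the Wald
#'   trend p-value with `term = "p_trend"`).
#' @export
hr_table <- function(cohort, exposures = c("sbp", "dbp", "wgrs"),
                     outcomes = c("uc_total", "uc_nonaggressive",
                                  "uc_aggressive"),
                     adjust = c("smoking", "bmi_quartile", "activity",
                                "education")) {
  purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(exposures, function(ex) {
      cat_fit <- fit_cox(cohort, exposure_spec(ex, "categorical"), oc, adjust)
      sd_fit <- fit_cox(cohort, exposure_spec(ex, "per_sd"), oc, adjust)
      tt <- trend_test(cohort, exposure_spec(ex, "categorical"), oc, adjust)
      keep_cat <- startsWith(names(cat_fit$coefficients),
                             cat_fit$exposure_terms)
      rows_cat <- tidy.bpgrs_cox(cat_fit, exponentiate = TRUE)[keep_cat, ]
      rows_sd <- tidy.bpgrs_cox(sd_fit, exponentiate = TRUE)
      rows_sd <- rows_sd[rows_sd$term == sd_fit$exposure_terms, ]
      dplyr::bind_rows(
        tibble::tibble(term = rows_cat$term, hr = rows_cat$estimate,
                       conf.low = rows_cat$conf.low,
                       conf.high = rows_cat$conf.high,
                       p.value = rows_cat$p.value,
                       n = cat_fit$n, n_events = cat_fit$n_events),
        tibble::tibble(term = "per_sd", hr = rows_sd$estimate,
                       conf.low = rows_sd$conf.low,
                       conf.high = rows_sd$conf.high,
                       p.value = rows_sd$p.value,
                       n = sd_fit$n, n_events = sd_fit$n_events),
        tibble::tibble(term = "p_trend", hr = NA_real_,
                       conf.low = NA_real_, conf.high = NA_real_,
                       p.value = tt$p.value,
                       n = cat_fit$n, n_events = cat_fit$n_events)
      ) |>
        dplyr::mutate(outcome = oc, exposure = ex, .before = 1)
    })
  })
}

#' Likelihood-ratio test for nested Cox models
#'
#' The restricted model must be nested in the full model (same analysis
#' sample; the full model's terms are the restricted terms plus the added
#' product term(s)). Used for multiplicative interaction.
#'
#' @param restricted,full `bpgrs_cox` fits on the same sample.
#' @return One-row tibble: `statistic` (2 x log-likelihood difference),
#'   `df` (number of added terms), `p.value` (chi-square upper tail).
#' @export
lr_test <- function(restricted, full) {
  if (restricted$n != full$n || restricted$n_events != full$n_events) {
    abort("models were fitted on different analysis samples")
  }
  added <- setdiff(names(full$coefficients), names(restricted$coefficients))
  lost <- setdiff(names(restricted$coefficients), names(full$coefficients))
  if (length(lost) > 0) {
    abort("restricted model is not nested in the full model")
  }
  stat <- 2 * (full$loglik[["model"]] - restricted$loglik[["model"]])
  if (stat < -1e-8) abort("full model has lower likelihood; models not nested")
  stat <- max(stat, 0)
  ## identical term sets: a degenerate but well-defined comparison (stat 0)
  p <- if (length(added) == 0) 1 else
    pchisq(stat, length(added), lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = length(added), p.value = p)
}
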