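#' Forest plot of joint-group hazard ratios
#'
#' Displays the four joint blood-pressure / score groups' hazard ratios
#' with 95% confidence intervals, annotated with the additive and
#' multiplicative interaction p-values.
#'
#' @param x A `reri_estimate` from [reri_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reri_estimate
#' @export
autoplot.reri_estimate <- function(x, ...) {
  if (is.null(x$group_hr)) {
    abort("this estimate carries no joint-group table (continuous scale?)")
  }
  gh <- x$group_hr
  gh$group <- factor(gh$group, levels = c("ref", "bp_only", "grs_only",
                                          "both"))
  lab <- sprintf("RERI %.2f (%.2f; %.2f)\np[add] = %.2g, p[multi] = %.2g",
                 x$reri, x$ci95[1], x$ci95[2], x$p_additive,
                 x$p_multiplicative)
  ggplot2::ggplot(gh, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Hazard ratio (95% CI)",
                  title = paste0(toupper(x$bp_var), " × genetic risk, ",
                                 x$outcome),
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Step plot of estimated cause-specific hazard rates
#'
#' @param x A `hazard_table` from [estimate_hazards()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hazard_table
#' @export
autoplot.hazard_table <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("age_start", "rate_event", "rate_death")],
    cols = c("rate_event", "rate_death"),
    names_to = "cause", values_to = "rate")
  long$cause <- ifelse(long$cause == "rate_event",
                       attr(x, "outcome") %||% "outcome", "death")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_start, y = .data$rate,
                                     colour = .data$cause)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Attained age (years)",
                  y = "Rate (events / person-year)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of group-wise absolute risks
#'
#' @param risks Tibble from [group_absolute_risks()].
#' @return A ggplot object.
#' @export
plot_absolute_risk <- function(risks) {
  risks$group <- factor(risks$group, levels = c("ref", "bp_only",
                                                "grs_only", "both"))
  p <- ggplot2::ggplot(risks, ggplot2::aes(x = .data$group,
                                           y = .data$risk_percent))
  if ("outcome" %in% names(risks)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$outcome),
                                 scales = "free_y")
  }
  p + ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%d-year absolute risk from age %d (%%)",
                  as.integer(risks$horizon[1]),
                  as.integer(risks$start_age[1]))) +
    ggplot2::theme_minimal()
}
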