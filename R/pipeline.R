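#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles every stage's knobs: where the cohort comes from (the synthetic
#' generator by default, or CSV/TSV inputs), which outcomes to model, the
#' blood-pressure thresholds, sensitivity cuts, continuous-scale increments,
#' and the absolute-risk window.
#'
#' @param sim A [sim_config()] for the synthetic generator, or `NULL` when
#'   reading external data.
#' @param cohort_csv,dosage_tsv,weights_tsv Paths to external inputs
#'   (ignored when `sim` is given; `weights_tsv = NULL` uses the bundled
#'   18-SNP table).
#' @param genotypes Run the genetic stages? `FALSE` restricts the pipeline
#'   to blood-pressure models only (the cohort-without-genotypes analysis
#'   arm).
#' @param outcomes Outcomes for the hazard-ratio table.
#' @param interaction_outcomes Outcomes for the interaction stage.
#' @param sensitivity_cuts_mmHg SBP thresholds for the RERI sensitivity
#'   analysis.
#' @param delta,sd_limit Continuous-scale RERI increments (SD units) and
#'   joint restriction window.
#' @param start_age,horizon Absolute-risk window (years).
#' @param adjust Adjustment covariates for all models.
#' @param seed Seed applied to the generator (overrides `sim$seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       cohort_csv = NULL, dosage_tsv = NULL,
                       weights_tsv = NULL,
                       genotypes = TRUE,
                       outcomes = c("uc_total", "uc_nonaggressive",
                                    "uc_aggressive"),
                       interaction_outcomes = c("uc_total",
                                                "uc_nonaggressive",
                                                "uc_aggressive"),
                       sensitivity_cuts_mmHg = c(130, 140, 150),
                       delta = c(1, 1), sd_limit = 2,
                       start_age = 60, horizon = 20,
                       adjust = c("smoking", "bmi_quartile", "activity",
                                  "education"),
                       seed = NULL) {
  if (is.null(sim) && is.null(cohort_csv)) {
    abort("run_config needs either a sim config or a cohort_csv path")
  }
  if (length(outcomes) == 0) abort("outcomes must be non-empty")
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, cohort_csv = cohort_csv,
                 dosage_tsv = dosage_tsv, weights_tsv = weights_tsv,
                 genotypes = genotypes, outcomes = outcomes,
                 interaction_outcomes = interaction_outcomes,
                 sensitivity_cuts_mmHg = sensitivity_cuts_mmHg,
                 delta = delta, sd_limit = sd_limit,
                 start_age = start_age, horizon = horizon,
                 adjust = adjust),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim:` block is
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
    names(y$sim)[names(y$sim) == "FALSE"] <- "n"
    if (!is.null(y$sim$baseline_age_range)) {
      y$sim$baseline_age_range <- as.numeric(y$sim$baseline_age_range)
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulate or read), build and
#' standardize the genetic risk score, fit the exposure hazard-ratio table,
#' run the additive/multiplicative interaction analyses for SBP and DBP
#' (binary and continuous scales), repeat the SBP analysis over sensitivity
#' cut points, and estimate 20-year absolute risks per joint group. All
#' tables are written as CSV under `out_dir` together with a JSON manifest
#' recording the seed and the exclusion bookkeeping (genotype-missing and
#' covariate-missing tallies). A failure in any stage aborts with the stage
#' name.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory results and `paths` of the
#'   files written.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("bpgrs_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  results <- list()

  ## --- data stage -----------------------------------------------------
  sim <- NULL
  data <- run_stage("data", {
    if (!is.null(config$sim)) {
      sim <- simulate_cohort(config$sim)
      list(cohort = sim$cohort, dosages = sim$dosages)
    } else {
      cohort <- readr::read_csv(config$cohort_csv, show_col_types = FALSE,
                                progress = FALSE)
      cohort$event <- factor(cohort$event,
                             levels = c("censored", .sim_causes))
      dosages <- if (!is.null(config$dosage_tsv)) {
        read_dosage_tsv(config$dosage_tsv)
      } else NULL
      list(cohort = cohort, dosages = dosages)
    }
  })
  cohort <- data$cohort
  n_total <- nrow(cohort)

  ## --- grs stage ------------------------------------------------------
  n_genotype_missing <- 0L
  if (config$genotypes && !is.null(data$dosages)) {
    scored <- run_stage("grs", {
      weights <- load_snp_weights(config$weights_tsv)
      suppressMessages(score_cohort(data$dosages, weights))
    })
    n_genotype_missing <- length(attr(scored, "excluded"))
    drop_cols <- intersect(c("raw_score", "z_score", "quartile",
                             "median_group", "wgrs_z"), names(cohort))
    cohort <- dplyr::left_join(cohort[, setdiff(names(cohort), drop_cols)],
                               scored, by = "id")
    results$scores <- scored
    paths$scores <- file.path(out_dir, "scores.csv")
    readr::write_csv(scored, paths$scores, progress = FALSE)
  } else {
    config$genotypes <- FALSE
  }

  ## --- survival models ------------------------------------------------
  exposures <- c("sbp", "dbp", if (config$genotypes) "wgrs")
  results$hr_table <- run_stage("survival", {
    hr_table(cohort, exposures, config$outcomes, config$adjust)
  })
  paths$hr_table <- file.path(out_dir, "hr_table.csv")
  readr::write_csv(results$hr_table, paths$hr_table, progress = FALSE)

  results$ph <- run_stage("survival", {
    purrr::map_dfr(config$outcomes, function(oc) {
      fit <- fit_cox(cohort, exposure_spec("sbp", "per_sd"), oc,
                     config$adjust)
      dplyr::mutate(ph_check(fit), outcome = oc, .before = 1)
    })
  })

  ## --- interaction stage ----------------------------------------------
  if (config$genotypes) {
    results$interaction <- run_stage("interaction", {
      purrr::map_dfr(c("sbp", "dbp"), function(bv) {
        purrr::map_dfr(config$interaction_outcomes, function(oc) {
          bin <- reri_analysis(cohort, oc, bv, adjust = config$adjust)
          cont <- reri_continuous(cohort, oc, bv, config$adjust,
                                  config$delta, config$sd_limit)
          dplyr::bind_rows(tidy.reri_estimate(bin),
                           tidy.reri_estimate(cont)) |>
            dplyr::mutate(bp_var = bv, outcome = oc, .before = 1)
        })
      })
    })
    paths$interaction <- file.path(out_dir, "interaction.csv")
    readr::write_csv(results$interaction, paths$interaction, progress = FALSE)

    results$sensitivity <- run_stage("sensitivity", {
      sensitivity_cuts(cohort, "uc_aggressive", "sbp",
                       config$sensitivity_cuts_mmHg, config$adjust)
    })
    paths$sensitivity <- file.path(out_dir, "sensitivity_sbp.csv")
    readr::write_csv(results$sensitivity, paths$sensitivity, progress = FALSE)

    results$absolute_risk <- run_stage("absolute_risk", {
      ch <- add_joint_groups(cohort, "sbp")
      purrr::map_dfr(c("uc_total", "uc_aggressive"), function(oc) {
        dplyr::mutate(
          group_absolute_risks(ch, oc, config$start_age, config$horizon),
          outcome = oc, .before = 1)
      })
    })
    paths$absolute_risk <- file.path(out_dir, "absolute_risk.csv")
    readr::write_csv(results$absolute_risk, paths$absolute_risk,
                     progress = FALSE)
  }

  ## --- manifest -------------------------------------------------------
  n_cov_missing <- sum(!stats::complete.cases(
    cohort[, intersect(config$adjust, names(cohort))]))
  genotyped <- if (config$genotypes) !is.na(cohort$raw_score) else
    rep(TRUE, n_total)
  n_model_genetic <- if (config$genotypes) {
    sum(genotyped & stats::complete.cases(
      cohort[, intersect(config$adjust, names(cohort))]))
  } else NA_integer_
  manifest <- list(
    package = "bpgrs",
    version = as.character(utils::packageVersion("bpgrs")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    n_total = n_total,
    n_genotype_missing = n_genotype_missing,
    n_covariate_missing = n_cov_missing,
    n_model_genetic = n_model_genetic,
    outcomes = config$outcomes,
    genotypes = config$genotypes
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  results$cohort <- cohort
  results$paths <- paths
  invisible(results)
}
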