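#' Compute the weighted genetic risk score
#'
#' For individual *i* with effect-allele dosages \eqn{d_{ix}} and per-SNP
#' log-odds weights \eqn{\beta_x}, the score is
#' \deqn{wGRS_i = \sum_x \beta_x d_{ix} / n_{SNP}.}
#' The division by the number of SNPs only rescales the score; it is kept so
#' raw scores are on the conventional per-SNP scale, and downstream z-scores
#' are invariant to it.
#'
#' @param dosages Dosage tibble (`id` + one numeric column per rsid), values
#'   in `[0, 2]` or `NA`.
#' @param weights Weight tibble from [load_snp_weights()].
#' @param missing_policy What to do with individuals carrying missing
#'   dosages: `"exclude"` (default) drops them from the result — mirroring a
#'   complete-genotype analysis — and reports how many were dropped;
#'   `"impute_eaf"` fills each missing dosage with its Hardy–Weinberg
#'   expectation `2 * eaf`.
#' @return A tibble with columns `id` and `raw_score`, one row per scored
#'   individual. The ids of excluded individuals are attached as attribute
#'   `"excluded"`.
#' @examples
#' w <- load_snp_weights()
#' d <- tibble::tibble(id = c("a", "b"))
#' for (r in w$rsid) d[[r]] <- c(0, 2)
#' compute_wgrs(d, w)$raw_score # 0 and 2 * sum(w$weight) / 18
#' @export
compute_wgrs <- function(dosages, weights,
                         missing_policy = c("exclude", "impute_eaf")) {
  missing_policy <- match.arg(missing_policy)
  dosages <- align_dosages(dosages, weights)
  m <- as.matrix(dosages[, weights$rsid, drop = FALSE])
  excluded <- character(0)
  if (anyNA(m)) {
    if (missing_policy == "exclude") {
      drop <- rowSums(is.na(m)) > 0
      excluded <- dosages$id[drop]
      inform(paste0(length(excluded),
                    " individual(s) with missing genotypes excluded"))
      m <- m[!drop, , drop = FALSE]
      dosages <- dosages[!drop, ]
    } else {
      exp_dose <- matrix(2 * weights$eaf, nrow(m), ncol(m), byrow = TRUE)
      m[is.na(m)] <- exp_dose[is.na(m)]
    }
  }
  out <- tibble::tibble(
    id = dosages$id,
    raw_score = as.numeric(m %*% weights$weight) / nrow(weights)
  )
  attr(out, "excluded") <- excluded
  out
}

#' Standardize a risk score to z-scores
#'
#' Adds `z_score = (x - mean(x)) / sd(x)` computed on the scored sample,
#' using the sample (n − 1) standard deviation.
#'
#' @param scores Tibble with a `raw_score` column (e.g. from
#'   [compute_wgrs()]); any other numeric column can be targeted via `var`.
#' @param var Column to standardize (default `raw_score`).
#' @return `scores` with a `z_score` column appended.
#' @export
standardize_score <- function(scores, var = "raw_score") {
  x <- scores[[var]]
  if (length(x[!is.na(x)]) < 2 || length(unique(x[!is.na(x)])) < 2) {
    abort("standardization needs >= 2 distinct values")
  }
  s <- sd(x, na.rm = TRUE)
  if (s == 0) abort("zero variance: cannot standardize")
  scores$z_score <- (x - mean(x, na.rm = TRUE)) / s
  scores
}

#' Assign quantile groups to a risk score
#'
#' Quartile cut points sit at the sample 25/50/75 percentiles; values equal
#' to a cut point fall in the lower group (deterministic tie rule). The
#' median scheme splits at the sample median into `lower50` / `upper50`.
#'
#' @param scores Tibble with a `raw_score` column.
#' @param scheme `"quartiles"`, `"median"`, or `"both"` (default).
#' @return `scores` with `quartile` (integer 1–4) and/or `median_group`
#'   (factor `lower50`/`upper50`) appended.
#' @export
assign_score_groups <- function(scores, scheme = c("both", "quartiles", "median")) {
  scheme <- match.arg(scheme)
  x <- scores$raw_score
  n <- sum(!is.na(x))
  if (scheme %in% c("both", "quartiles")) {
    if (n < 4) abort("fewer individuals than quartile groups")
    cuts <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    # count of cut points strictly below x: ties fall in the lower group,
    # and duplicated cut points (heavy ties) degrade gracefully
    scores$quartile <- 1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
  }
  if (scheme %in% c("both", "median")) {
    if (n < 2) abort("fewer individuals than median groups")
    med <- median(x, na.rm = TRUE)
    scores$median_group <- factor(ifelse(x <= med, "lower50", "upper50"),
                                  levels = c("lower50", "upper50"))
  }
  scores
}

#' Score a cohort end to end
#'
#' Convenience wrapper: computes the wGRS from dosages, standardizes it on
#' the scored sample (after any missing-genotype exclusions), and assigns
#' quartile and median groups.
#'
#' @inheritParams compute_wgrs
#' @return Tibble `id`, `raw_score`, `z_score`, `quartile`, `median_group`,
#'   with excluded ids in attribute `"excluded"`.
#' @export
score_cohort <- function(dosages, weights = load_snp_weights(),
                         missing_policy = c("exclude", "impute_eaf")) {
  s <- compute_wgrs(dosages, weights, missing_policy)
  excluded <- attr(s, "excluded")
  s <- assign_score_groups(standardize_score(s), "both")
  attr(s, "excluded") <- excluded
  s
}
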