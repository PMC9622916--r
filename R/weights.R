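#' Load a SNP weight table for the bladder-cancer genetic risk score
#'
#' Reads a tab-separated weight table with one row per variant. The table must
#' carry the variant identifier, effect and other allele, effect-allele
#' frequency and per-allele odds ratio; the log-odds weight is always
#' recomputed at full precision as `log(or)`. When the file also carries a
#' printed `ln_or` column, the recomputed weight is validated against it to
#' within `1e-6` (printed tables typically round to six decimals), so a
#' transcription error in either column is caught at load time.
#'
#' @param path Path to a TSV file with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `or`, and optionally `ln_or` and `gene`. `NULL`
#'   (the default) loads the weight table bundled with the package: 18
#'   bladder-cancer susceptibility variants from European-ancestry GWAS.
#' @return A tibble with one row per SNP and columns `rsid`, `gene` (may be
#'   `NA`), `effect_allele`, `other_allele`, `eaf`, `or` and `weight`
#'   (natural log of `or`).
#' @examples
#' w <- load_snp_weights()
#' nrow(w) # 18
#' @export
load_snp_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bc_snp_weights.tsv", package = "bpgrs")
  }
  if (!file.exists(path)) {
    abort(paste0("weight table not found: ", path))
  }
  w <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("rsid", "effect_allele", "other_allele", "eaf", "or")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols) > 0) {
    abort(paste0("weight table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(w$rsid)) {
    dup <- unique(w$rsid[duplicated(w$rsid)])
    abort(paste0("duplicate rsid(s) in weight table: ",
                 paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(w$or) | w$or <= 0)) {
    abort("odds ratios must be finite and > 0")
  }
  if (any(!is.finite(w$eaf) | w$eaf <= 0 | w$eaf >= 1)) {
    abort("effect-allele frequencies must lie strictly inside (0, 1)")
  }
  if (any(w$effect_allele == w$other_allele)) {
    abort("effect_allele and other_allele must differ")
  }
  w$weight <- log(w$or)
  if ("ln_or" %in% names(w)) {
    off <- abs(w$weight - w$ln_or) >= 1e-6
    if (any(off)) {
      abort(paste0("printed ln(OR) disagrees with log(OR) beyond 1e-6 for: ",
                   paste(w$rsid[off], collapse = ", ")))
    }
    w$ln_or <- NULL
  }
  if (!"gene" %in% names(w)) w$gene <- NA_character_
  tibble::as_tibble(w[, c("rsid", "gene", "effect_allele", "other_allele",
                          "eaf", "or", "weight")])
}

#' Write a SNP weight table
#'
#' Writes the weight table back to TSV at full precision, so that a
#' write/read round trip reproduces every (rsid, OR, weight) triple
#' bit-identically.
#'
#' @param weights A weight tibble as returned by [load_snp_weights()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_weights <- function(weights, path) {
  stopifnot(all(c("rsid", "effect_allele", "other_allele", "eaf", "or")
                %in% names(weights)))
  out <- weights[, intersect(c("rsid", "gene", "effect_allele", "other_allele",
                               "eaf", "or"), names(weights))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
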