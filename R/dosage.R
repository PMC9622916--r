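#' Read a genotype dosage matrix from TSV
#'
#' Expects one row per individual: an `id` column (first column, any name)
#' followed by one column per variant, holding expected effect-allele counts
#' in `[0, 2]`. Missing genotypes may be empty or `NA`.
#'
#' @param path TSV file path.
#' @return A tibble whose first column is `id` (character) and remaining
#'   columns are numeric dosages named by rsid.
#' @export
read_dosage_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 2) abort("dosage table needs an id column plus >= 1 variant")
  names(d)[1] <- "id"
  d$id <- as.character(d$id)
  for (j in seq(2, ncol(d))) d[[j]] <- as.numeric(d[[j]])
  check_dosage_range(d)
  tibble::as_tibble(d)
}

#' Read genotype dosages from a VCF file
#'
#' Uses the `DS` (imputed dosage) FORMAT field when present; otherwise falls
#' back to hard genotype calls (`GT`), counting ALT alleles as 0/1/2. Dosages
#' are reported on the effect-allele scale of the supplied weight table: a
#' variant whose ALT allele is the weight table's *other* allele is flipped to
#' `2 - dosage`; a variant whose alleles match neither orientation raises an
#' error.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param weights Weight tibble from [load_snp_weights()]; only variants
#'   present in it are returned.
#' @return A dosage tibble as from [read_dosage_tsv()].
#' @export
read_dosage_vcf <- function(path, weights) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rsids <- names(SummarizedExperiment::rowRanges(vcf))
  keep <- rsids %in% weights$rsid
  if (!any(keep)) abort("no weight-table variants found in VCF")
  vcf <- vcf[keep, ]
  rsids <- rsids[keep]
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    ds <- geno$DS # variants x samples
    mode(ds) <- "numeric"
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  } else {
    abort("VCF has neither DS nor GT genotype fields")
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], character(1))
  w <- weights[match(rsids, weights$rsid), ]
  flip <- alt == w$other_allele & ref == w$effect_allele
  straight <- alt == w$effect_allele & ref == w$other_allele
  bad <- !flip & !straight
  if (any(bad)) {
    abort(paste0("VCF alleles match neither orientation of the weight table",
                 " for: ", paste(rsids[bad], collapse = ", ")))
  }
  ds[flip, ] <- 2 - ds[flip, , drop = FALSE]
  out <- tibble::tibble(id = colnames(ds))
  for (i in seq_along(rsids)) out[[rsids[i]]] <- unname(ds[i, ])
  check_dosage_range(out)
  out
}

#' Align a dosage matrix to a weight table
#'
#' Reorders dosage columns to the weight-table order and verifies that every
#' weighted variant is present and every dosage lies in `[0, 2]` (or is
#' missing).
#'
#' @param dosages Dosage tibble (`id` + one column per rsid).
#' @param weights Weight tibble from [load_snp_weights()].
#' @return The dosage tibble with variant columns in weight-table order.
#' @export
align_dosages <- function(dosages, weights) {
  miss <- setdiff(weights$rsid, names(dosages))
  if (length(miss) > 0) {
    abort(paste0("dosage matrix lacks weighted variant(s): ",
                 paste(miss, collapse = ", ")))
  }
  check_dosage_range(dosages)
  dosages[, c("id", weights$rsid)]
}

check_dosage_range <- function(dosages) {
  m <- as.matrix(dosages[, setdiff(names(dosages), "id"), drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) abort("negative dosage encountered")
  if (any(m > 2, na.rm = TRUE)) abort("dosage above 2 encountered")
  invisible(dosages)
}
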