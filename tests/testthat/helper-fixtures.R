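# shared fixtures: tiny weight tables, fast simulator configs, and the
# brute-force partial-likelihood oracle used against the Cox engine

`%||%` <- function(x, y) if (is.null(x)) y else x

bundled_weights_path <- function() {
  system.file("extdata", "bc_snp_weights.tsv", package = "bpgrs")
}

# 3-variant weight table written to a temp TSV
tiny_weights_file <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny_weights.tsv")
  readr::write_tsv(tibble::tibble(
    rsid = c("rsA", "rsB", "rsC"),
    effect_allele = c("T", "A", "C"),
    other_allele = c("C", "G", "T"),
    eaf = c(0.3, 0.5, 0.8),
    or = c(1.2, 1.0, 0.9)
  ), path, progress = FALSE)
  path
}

# simulator config with elevated aggressive-UC hazard and no masking, so
# replicate tests get plenty of events at small n
quick_cfg <- function(n, seed, joint_rr = NULL, effects = NULL,
                      agg_rate = 9.7e-4) {
  sim_config(
    n = n, seed = seed,
    n_genotype_missing = 0L, n_bmi_missing = 0L, n_education_missing = 0L,
    joint_rr = joint_rr,
    effects = effects %||% list(uc_nonaggressive = NULL,
                                uc_aggressive = NULL, death = NULL),
    hazard = list(uc_nonaggressive = list(rate60 = 3.15e-4, slope = 0.08),
                  uc_aggressive = list(rate60 = agg_rate, slope = 0.08),
                  death = list(rate60 = 7.5e-3, slope = 0.09))
  )
}

# Breslow-form partial log-likelihood by explicit risk-set enumeration;
# exact for untied event times. Risk set at event age t: entry < t <= exit.
bf_cox_loglik <- function(entry, exit, status, X, beta) {
  X <- as.matrix(X)
  lp <- as.numeric(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    t_i <- exit[i]
    rs <- which(entry < t_i & exit >= t_i)
    ll <- ll + lp[i] - log(sum(exp(lp[rs])))
  }
  ll
}

# minimal fake Cox fit carrying joint-group coefficients and covariance,
# for exercising the RERI arithmetic on known inputs
fake_joint_fit <- function(b10, b01, b11, vc = diag(1e-4, 3)) {
  nm <- paste0("joint_group", c("bp_only", "grs_only", "both"))
  dimnames(vc) <- list(nm, nm)
  structure(list(coefficients = setNames(c(b10, b01, b11), nm), vcov = vc,
                 loglik = c(null = NA, model = NA), n = NA, n_events = NA),
            class = "bpgrs_cox")
}
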