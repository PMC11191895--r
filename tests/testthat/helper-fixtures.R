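# Fixture builders used across test files.

# A harmonized set built directly from effect vectors (already aligned).
make_harmonized <- function(bx, sx, by, sy, snp_id = NULL, bm = NULL,
                            sm = NULL) {
  k <- length(bx)
  if (is.null(snp_id)) snp_id <- sprintf("rs%03d", seq_len(k))
  df <- data.frame(snp_id = snp_id,
                   effect_allele = "A", other_allele = "G",
                   beta_exposure = bx, se_exposure = sx,
                   eaf_exposure = 0.3, pval_exposure = 1e-8,
                   stringsAsFactors = FALSE)
  if (!is.null(bm)) {
    df$beta_mediator <- bm
    df$se_mediator <- sm
  }
  df$beta_outcome <- by
  df$se_outcome <- sy
  studies <- c(if (!is.null(bm)) "mediator", "outcome")
  structure(df, studies = studies,
            class = c("harmonized_set", "data.frame"))
}

make_sumstats <- function(snp_id, effect_allele = "A", other_allele = "G",
                          beta = 0.1, se = 0.02, pval = NULL, eaf = 0.3,
                          n = 10000) {
  k <- length(snp_id)
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  sumstats(snp_id = snp_id, effect_allele = rep_len(effect_allele, k),
           other_allele = rep_len(other_allele, k),
           beta = rep_len(beta, k), se = rep_len(se, k),
           pval = pmax(rep_len(pval, k), 1e-300),
           eaf = rep_len(eaf, k), n = rep_len(n, k))
}

# Write a small sumstats-like table to a temp TSV and return the path.
write_fixture_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
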