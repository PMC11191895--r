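#' Instrument-selection configuration
#'
#' Bundles the thresholds used to pick instrumental variables: the genome-wide
#' p-value cut (1e-5 by default, the conventional relaxed threshold for
#' microbiome exposures; 5e-6 is typical for protein exposures), the greedy
#' LD-clumping window (+/- 10,000 kb) and r-squared ceiling (0.001), and the
#' minimum F-statistic (10) below which an instrument is deemed weak and
#' excluded.
#'
#' @param pval_threshold instrument p-value cut, strictly applied
#'   (`pval < threshold`).
#' @param clump_window_kb half-width of the clumping window in kb.
#' @param clump_r2 r-squared at or above which two SNPs in the window are in
#'   the same clump.
#' @param f_min minimum F-statistic; instruments with F below it are weak.
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(pval_threshold = 1e-5, clump_window_kb = 10000,
                              clump_r2 = 0.001, f_min = 10) {
  stopifnot(pval_threshold > 0, clump_window_kb > 0,
            clump_r2 > 0, clump_r2 < 1, f_min >= 0)
  structure(list(pval_threshold = pval_threshold,
                 clump_window_kb = clump_window_kb,
                 clump_r2 = clump_r2, f_min = f_min),
            class = "instrument_config")
}

#' Filter records by p-value threshold
#'
#' Keeps exactly the records with `pval < threshold` (strict), preserving
#' input order.
#'
#' @param records a `sumstats` table.
#' @param threshold p-value cut.
#' @return The filtered `sumstats` table (possibly empty).
#' @export
select_by_pvalue <- function(records, threshold) {
  stopifnot(threshold > 0)
  out <- records[records$pval < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining SNP with the smallest p-value (ties broken
#' by lexicographically smallest `snp_id`) and removes every other remaining
#' SNP on the same chromosome within `window_kb` kb whose r-squared with it
#' is at least `r2_max`.  Pairs beyond the window or absent from the LD
#' reference count as r-squared 0, so SNPs on different chromosomes never
#' clump together.  The result is deterministic and independent of input
#' order.
#'
#' @param records a `sumstats` table.
#' @param ld an [ld_reference()]; every record must have a position in it.
#' @param window_kb half-width of the window in kb.
#' @param r2_max r-squared threshold.
#' @return The retained `sumstats` rows, ordered by ascending p-value (ties
#'   by `snp_id`).
#' @export
clump <- function(records, ld, window_kb = 10000, r2_max = 0.001) {
  if (nrow(records) == 0L) return(records)
  pos <- ld_positions(ld, records$snp_id)  # errors on missing positions
  ord <- order(records$pval, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  pos <- pos[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & pos$chrom == pos$chrom[i] &
                    abs(pos$pos - pos$pos[i]) <= window_bp)
    if (length(cand) > 0L) {
      r2 <- ld_r2(ld, rec$snp_id[i], rec$snp_id[cand])
      alive[cand[r2 >= r2_max]] <- FALSE
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F-statistic
#'
#' The default per-SNP approximation is `(beta/se)^2`, computable from the
#' summary statistics alone.  When `method = "n_based"` the classical form
#' `(n - 2) R^2 / (1 - R^2)` is used, with the variance explained
#' approximated as `R^2 = 2 f (1 - f) beta^2` for effect-allele frequency
#' `f` on a unit-variance trait; it requires `n` and `eaf`.
#'
#' @param records a `sumstats` table.
#' @param method `"ratio"` (default) or `"n_based"`.
#' @return Numeric vector of F-statistics, one per record.
#' @export
f_statistic <- function(records, method = c("ratio", "n_based")) {
  method <- match.arg(method)
  if (method == "ratio") {
    return((records$beta / records$se)^2)
  }
  if (anyNA(records$n) || anyNA(records$eaf)) {
    stop("n_based F-statistic requires sample size and eaf for every record")
  }
  r2 <- 2 * records$eaf * (1 - records$eaf) * records$beta^2
  (records$n - 2) * r2 / (1 - r2)
}

#' Exclude weak instruments
#'
#' Instruments with F below `f_min` (conventionally 10) are weak and removed;
#' the weak rows are reported in the `weak` attribute.
#'
#' @param records a `sumstats` table.
#' @param f_min minimum F-statistic.
#' @param method passed to [f_statistic()].
#' @return The strong rows; attribute `weak` holds the excluded rows with
#'   their F values.
#' @export
filter_weak_instruments <- function(records, f_min = 10, method = "ratio") {
  f <- f_statistic(records, method)
  weak <- records[f < f_min, , drop = FALSE]
  weak$f_stat <- f[f < f_min]
  out <- records[f >= f_min, , drop = FALSE]
  out$f_stat <- f[f >= f_min]
  rownames(out) <- NULL
  structure(out, weak = weak, class = class(records))
}

#' Select instrumental variables for one exposure
#'
#' Applies the full instrument-selection cascade: strict p-value filter,
#' greedy LD clumping within the distance window, and weak-instrument
#' exclusion by F-statistic.
#'
#' @param records the exposure's full `sumstats` table.
#' @param ld an [ld_reference()].
#' @param config an [instrument_config()].
#' @return The selected instruments (a `sumstats` table with an `f_stat`
#'   column); attribute `weak` lists instruments dropped as weak.
#' @export
select_instruments <- function(records, ld, config = instrument_config()) {
  sig <- select_by_pvalue(records, config$pval_threshold)
  cl <- clump(sig, ld, config$clump_window_kb, config$clump_r2)
  filter_weak_instruments(cl, config$f_min)
}
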