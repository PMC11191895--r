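#' Build a joint instrument set for multivariable MR
#'
#' Pools the instruments selected separately for the exposure and the
#' mediator, de-duplicates, re-clumps the pooled list jointly (same window
#' and r-squared as univariable selection, ranking SNPs by the smaller of
#' their exposure and mediator p-values), re-extracts each surviving SNP's
#' associations from the full summary statistics of the exposure, the
#' mediator and the outcome, and harmonizes the three to a shared effect
#' allele.  A pooled SNP absent from any full table is dropped with reason
#' `"missing"`, never imputed.
#'
#' @param exposure_iv,mediator_iv instruments from each trait's own
#'   selection run (`sumstats` tables).
#' @param exposure_full,mediator_full,outcome_full full summary-statistics
#'   tables for re-extraction.
#' @param ld an [ld_reference()].
#' @param config an [instrument_config()] supplying the clumping window and
#'   r-squared.
#' @param palindrome_maf_limit passed to [harmonize()].
#' @return A `harmonized_set` with aligned `mediator` and `outcome` columns.
#' @export
build_joint_instruments <- function(exposure_iv, mediator_iv, exposure_full,
                                    mediator_full, outcome_full, ld,
                                    config = instrument_config(),
                                    palindrome_maf_limit = 0.42) {
  ids <- union(exposure_iv$snp_id, mediator_iv$snp_id)
  exp_rows <- exposure_full[match(ids, exposure_full$snp_id), , drop = FALSE]
  med_rows <- mediator_full[match(ids, mediator_full$snp_id), , drop = FALSE]
  present <- !is.na(exp_rows$snp_id)
  pooled <- exp_rows[present, , drop = FALSE]
  # rank the pooled greedy pass by the best evidence in either trait
  med_p <- med_rows$pval[present]
  pooled$pval <- pmin(pooled$pval, med_p, na.rm = TRUE)
  clumped <- clump(pooled, ld, config$clump_window_kb, config$clump_r2)
  exp_sel <- exposure_full[exposure_full$snp_id %in% clumped$snp_id, ,
                           drop = FALSE]
  h <- harmonize(exp_sel,
                 list(mediator = mediator_full, outcome = outcome_full),
                 palindrome_maf_limit)
  if (any(!present)) {
    attr(h, "dropped") <- rbind(
      attr(h, "dropped"),
      data.frame(snp_id = ids[!present], reason = "missing",
                 stringsAsFactors = FALSE))
  }
  h
}

mvmr_sub_fit <- function(X, by, w, k) {
  p <- ncol(X)
  xtwx <- crossprod(X, w * X)
  betas <- drop(solve(xtwx, crossprod(X, w * by)))
  resid <- by - drop(X %*% betas)
  phi <- max(1, sqrt(sum(w * resid^2) / (k - p)))
  ses <- sqrt(diag(solve(xtwx))) * phi
  list(betas = betas, ses = ses,
       pvals = 2 * stats::pnorm(-abs(betas / ses)))
}

#' Multivariable inverse-variance-weighted MR
#'
#' Weighted multiple linear regression, without intercept, of the
#' instrument-outcome effects on the matrix of instrument-exposure effects
#' with weights `sy^-2`.  Each coefficient is that exposure's effect on the
#' outcome adjusted for the others (in the mediation workflow the mediator's
#' coefficient is the adjusted mediator effect and the exposure's the direct
#' effect).  Standard errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(RSS_w / (k - p)))`; p-values are two-sided normal.  A
#' conditional instrument-strength F-statistic per exposure is reported as a
#' diagnostic: the weighted residual sum of squares from regressing that
#' exposure's instrument effects (standardized by their SEs) on the other
#' exposures', divided by `k - p + 1`.
#'
#' @param h a `harmonized_set` carrying one `beta_`/`se_` column pair per
#'   exposure plus the outcome.
#' @param exposures character vector naming the exposure columns in the
#'   design, in order (default: every aligned study except the outcome).
#' @param outcome the outcome column name (default `"outcome"`).
#' @return An object of class `mvmr_result` with `exposures`, `betas`,
#'   `ses`, `pvals`, `n_snps`, `conditional_f`.
#' @export
mvmr_ivw <- function(h, exposures = NULL, outcome = "outcome") {
  if (is.null(exposures)) {
    studies <- attr(h, "studies")
    all_traits <- c("exposure", if (!is.null(studies)) studies else
      setdiff(sub("^beta_", "", grep("^beta_", names(h), value = TRUE)),
              "exposure"))
    exposures <- setdiff(all_traits, outcome)
  }
  p <- length(exposures)
  if (p < 2L) stop("multivariable MR needs at least 2 exposures")
  X <- as.matrix(as.data.frame(h)[, paste0("beta_", exposures), drop = FALSE])
  SX <- as.matrix(as.data.frame(h)[, paste0("se_", exposures), drop = FALSE])
  by <- h[[paste0("beta_", outcome)]]
  sy <- h[[paste0("se_", outcome)]]
  k <- nrow(X)
  if (k <= p) stop("need more instruments (", k, ") than exposures (", p, ")")
  w <- sy^-2
  # an exposure with no instrument effects at all contributes nothing to the
  # design; its coefficient is unidentified and reported as NA, and the
  # regression reduces to the nested model on the remaining exposures
  live <- colSums(X != 0) > 0L
  if (sum(live) == 0L) stop("all exposure effect columns are zero")
  if (any(!live)) {
    sub <- mvmr_sub_fit(X[, live, drop = FALSE], by, w, k)
    betas <- ses <- pvals <- rep(NA_real_, p)
    betas[live] <- sub$betas
    ses[live] <- sub$ses
    pvals[live] <- sub$pvals
    return(structure(list(
      exposures = exposures,
      betas = stats::setNames(betas, exposures),
      ses = stats::setNames(ses, exposures),
      pvals = stats::setNames(pvals, exposures),
      n_snps = k,
      conditional_f = stats::setNames(rep(NA_real_, p), exposures)
    ), class = "mvmr_result"))
  }
  xtwx <- crossprod(X, w * X)
  cn <- kappa(xtwx, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12) {
    stop("collinear exposure effects in MVMR design (condition number ",
         format(cn, digits = 3), ")")
  }
  xtwy <- crossprod(X, w * by)
  betas <- drop(solve(xtwx, xtwy))
  resid <- by - drop(X %*% betas)
  rss_w <- sum(w * resid^2)
  phi <- max(1, sqrt(rss_w / (k - p)))
  ses <- sqrt(diag(solve(xtwx))) * phi
  pvals <- 2 * stats::pnorm(-abs(betas / ses))

  cond_f <- vapply(seq_len(p), function(i) {
    z <- X[, i] / SX[, i]
    Z <- X[, -i, drop = FALSE] / SX[, i]
    coef_i <- solve(crossprod(Z), crossprod(Z, z))
    q_x <- sum((z - drop(Z %*% coef_i))^2)
    q_x / (k - p + 1)
  }, numeric(1))

  structure(list(
    exposures = exposures,
    betas = stats::setNames(betas, exposures),
    ses = stats::setNames(ses, exposures),
    pvals = stats::setNames(pvals, exposures),
    n_snps = k,
    conditional_f = stats::setNames(cond_f, exposures)
  ), class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable IVW on %d instruments:\n", x$n_snps))
  print(data.frame(exposure = x$exposures, beta = x$betas, se = x$ses,
                   pval = x$pvals, conditional_f = x$conditional_f,
                   row.names = NULL))
  invisible(x)
}
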