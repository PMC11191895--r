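#' Replication meta-analysis of MR estimates
#'
#' Pools two or more per-study causal estimates of the same
#' exposure-outcome pair.  The fixed-effects model uses inverse-variance
#' weights `se^-2`; the random-effects model uses the DerSimonian-Laird
#' between-study variance `tau2 = max(0, (Q - (m-1)) / (sum(w) -
#' sum(w^2)/sum(w)))` with adjusted weights `(se^2 + tau2)^-1`.  With
#' `model = "auto"` the random model is used exactly when the cross-study
#' Q p-value is below 0.05 (heterogeneous replication), the fixed model
#' otherwise.  Fitting is delegated to [metafor::rma.uni()].
#'
#' @param estimates a list of `mr_estimate` objects, or a data.frame with
#'   columns `beta` and `se`, one row/element per study (at least 2).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return An object of class `meta_result`: `beta_pooled`, `se_pooled`,
#'   `pval_pooled`, `model`, `tau2`, `q_between`, `q_between_pval`,
#'   `inputs`.
#' @export
meta_analyze <- function(estimates, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  if (is.data.frame(estimates)) {
    betas <- estimates$beta
    ses <- estimates$se
  } else {
    betas <- vapply(estimates, function(e) e$beta, numeric(1))
    ses <- vapply(estimates, function(e) e$se, numeric(1))
  }
  m <- length(betas)
  if (m < 2L) stop("meta-analysis needs at least 2 study estimates")
  fe <- metafor::rma.uni(yi = betas, sei = ses, method = "FE")
  q <- as.numeric(fe$QE)
  q_pval <- as.numeric(fe$QEp)
  used <- switch(model,
                 fixed = "fixed", random = "random",
                 auto = if (q_pval < 0.05) "random" else "fixed")
  fit <- if (used == "random") {
    metafor::rma.uni(yi = betas, sei = ses, method = "DL")
  } else {
    fe
  }
  structure(list(
    beta_pooled = as.numeric(fit$beta),
    se_pooled = as.numeric(fit$se),
    pval_pooled = as.numeric(fit$pval),
    model = used,
    tau2 = if (used == "random") as.numeric(fit$tau2) else 0,
    q_between = q,
    q_between_pval = q_pval,
    inputs = data.frame(beta = betas, se = ses)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s effects, %d studies): beta = %.4f (se %.4f), p = %.3g\n",
              x$model, nrow(x$inputs), x$beta_pooled, x$se_pooled,
              x$pval_pooled))
  cat(sprintf("  between-study Q = %.3f (p = %.3g), tau^2 = %.4g\n",
              x$q_between, x$q_between_pval, x$tau2))
  invisible(x)
}

#' Proportion of an effect transmitted through a mediator
#'
#' `indirect / (indirect + direct)`, the share of the total effect carried
#' by the mediated path.
#'
#' @param indirect the mediated (indirect) effect, `beta1 * beta4`.
#' @param direct the direct effect, `beta5`.
#' @return The proportion mediated (a raw fraction, possibly negative or
#'   above 1 when paths oppose); an error if the total effect is zero.
#' @export
proportion_mediated <- function(indirect, direct) {
  total <- indirect + direct
  if (total == 0) stop("proportion mediated undefined: total effect is zero")
  indirect / total
}

#' Two-step MR mediation decomposition
#'
#' Combines the univariable exposure-to-mediator effect (`beta1`) with the
#' multivariable-MR mutually adjusted effects of the mediator (`beta4`) and
#' the exposure (`beta5`) on the outcome.  The mediated (indirect) effect is
#' `beta1 * beta4`, the total effect is `beta1 * beta4 + beta5`, and the
#' proportion mediated is their ratio.  A mediation is established only when
#' the indirect and total effects point in the same direction and (when
#' p-values are supplied) both mediator-path links `beta1` and `beta4` are
#' significant at `alpha`; the direct effect's significance is deliberately
#' not gated on.  A delta-method SE for the indirect effect,
#' `sqrt(beta4^2 se1^2 + beta1^2 se4^2)`, and a delta-method CI for the
#' proportion (assuming independent inputs) are reported as diagnostics.
#'
#' The univariable mediator-to-outcome (`beta2`) and exposure-to-outcome
#' (`beta3`) estimates can be attached for context; they do not enter the
#' decomposition.
#'
#' @param beta1 exposure-to-mediator effect (univariable IVW).
#' @param beta4 mediator-to-outcome effect adjusted for the exposure (MVMR).
#' @param beta5 exposure-to-outcome effect adjusted for the mediator (MVMR).
#' @param se1,se4,se5 standard errors (optional; enable the diagnostics).
#' @param p1,p4,p5 p-values (optional; `p1`/`p4` enable significance
#'   gating of `established`).
#' @param beta2,beta3 optional univariable context estimates.
#' @param alpha significance level for the mediator-path gate.
#' @return An object of class `mediation_decomposition` with fields
#'   `beta1`..`beta5`, `indirect`, `total`, `proportion`,
#'   `proportion_label`, `established`, `indirect_se`, `proportion_ci`.
#' @export
decompose_mediation <- function(beta1, beta4, beta5,
                                se1 = NA_real_, se4 = NA_real_,
                                se5 = NA_real_,
                                p1 = NA_real_, p4 = NA_real_, p5 = NA_real_,
                                beta2 = NA_real_, beta3 = NA_real_,
                                alpha = 0.05) {
  stopifnot(is.finite(beta1), is.finite(beta4), is.finite(beta5))
  indirect <- beta1 * beta4
  total <- indirect + beta5
  if (total == 0) stop("proportion mediated undefined: total effect is zero")
  proportion <- proportion_mediated(indirect, beta5)
  sign_ok <- sign(indirect) == sign(total)
  sig_ok <- (is.na(p1) || p1 < alpha) && (is.na(p4) || p4 < alpha)
  established <- sign_ok && sig_ok
  indirect_se <- sqrt(beta4^2 * se1^2 + beta1^2 * se4^2)
  proportion_ci <- c(NA_real_, NA_real_)
  if (!anyNA(c(se1, se4, se5))) {
    d1 <- beta4 * beta5 / total^2
    d4 <- beta1 * beta5 / total^2
    d5 <- -indirect / total^2
    prop_se <- sqrt(d1^2 * se1^2 + d4^2 * se4^2 + d5^2 * se5^2)
    proportion_ci <- proportion + c(-1, 1) * stats::qnorm(0.975) * prop_se
  }
  structure(list(
    beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
    beta5 = beta5, p1 = p1, p4 = p4, p5 = p5,
    indirect = indirect, total = total,
    proportion = proportion,
    proportion_label = if (established) format_proportion(proportion)
                       else NA_character_,
    established = established,
    indirect_se = indirect_se,
    proportion_ci = proportion_ci
  ), class = "mediation_decomposition")
}

#' Format a mediation proportion for reporting
#'
#' One decimal place below 10 percent, integer percent otherwise (so 0.083
#' prints as "8.3%" and 0.184 as "18%"); the raw fraction should always be
#' kept alongside.
#'
#' @param p proportion as a fraction.
#' @return A character label.
#' @export
format_proportion <- function(p) {
  pct <- 100 * p
  if (abs(pct) < 10) sprintf("%.1f%%", pct) else sprintf("%.0f%%", pct)
}

#' @export
print.mediation_decomposition <- function(x, ...) {
  cat(sprintf("Mediation decomposition: beta1 = %.3f, beta4 = %.3f, beta5 = %.3f\n",
              x$beta1, x$beta4, x$beta5))
  cat(sprintf("  indirect = %.4f, total = %.4f\n", x$indirect, x$total))
  if (x$established) {
    cat(sprintf("  proportion mediated = %s (raw %.4f)\n",
                x$proportion_label, x$proportion))
  } else {
    cat("  mediation not established (opposite directions or non-significant mediator path)\n")
  }
  invisible(x)
}

#' Screen exposure-outcome pairs for mediation candidacy
#'
#' A pair is a candidate exactly when (1) the IVW estimate is significant at
#' `alpha`, (2) the IVW, MR-Egger and weighted-median effects all point in
#' the same direction, (3) the MR-PRESSO global test shows no pleiotropy
#' (`global_pval >= presso_alpha`), and (4) the replication meta-analysis is
#' significant at `alpha`.  Each excluded pair is annotated with the first
#' failing rule, in that order.
#'
#' @param results a data.frame with one row per pair and columns `exposure`,
#'   `outcome`, `ivw_beta`, `ivw_pval`, `egger_beta`, `wm_beta`,
#'   `presso_global_pval`, `meta_pval`.
#' @param alpha nominal significance level (default 0.05; the screen uses
#'   nominal p-values without multiple-testing correction, matching common
#'   discovery practice in this workflow).
#' @param presso_alpha MR-PRESSO global-test threshold (default 0.05).
#' @return `results` with added columns `candidate` (logical) and `reason`
#'   (`"pass"` or the first failing rule).
#' @export
screen_candidates <- function(results, alpha = 0.05, presso_alpha = 0.05) {
  required <- c("exposure", "outcome", "ivw_beta", "ivw_pval", "egger_beta",
                "wm_beta", "presso_global_pval", "meta_pval")
  missing_cols <- setdiff(required, names(results))
  if (length(missing_cols) > 0L) {
    stop("screening table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(results[, required])
  if (any(bad)) {
    i <- which(bad)[1]
    stage <- required[which(is.na(results[i, required]))[1]]
    stop("pair ", results$exposure[i], " -> ", results$outcome[i],
         " is missing stage input '", stage, "'")
  }
  reason <- rep("pass", nrow(results))
  fail <- function(cond, label) {
    reason[reason == "pass" & cond] <<- label
  }
  fail(results$ivw_pval >= alpha, "ivw not significant")
  fail(sign(results$egger_beta) != sign(results$ivw_beta) |
         sign(results$wm_beta) != sign(results$ivw_beta),
       "direction disagreement")
  fail(results$presso_global_pval < presso_alpha, "pleiotropy detected")
  fail(results$meta_pval >= alpha, "meta-analysis not significant")
  results$candidate <- reason == "pass"
  results$reason <- reason
  results
}
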