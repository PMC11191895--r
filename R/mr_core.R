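#' @keywords internal
mr_estimate <- function(method, beta, se, n_snps, pval = NULL, df = NULL,
                        q = NA_real_, q_pval = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_pval = NA_real_,
                        effects_model = NA_character_) {
  if (is.null(pval)) {
    z <- beta / se
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(z)) else
      2 * stats::pt(-abs(z), df = df)
  }
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df = df)
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval,
    or_ = exp(beta), or_ci = c(exp(ci_low), exp(ci_high)),
    n_snps = n_snps, q = q, q_pval = q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_pval = egger_intercept_pval,
    effects_model = effects_model
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s%s): beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, OR = %.3f\n",
              x$method,
              if (!is.na(x$effects_model)) paste0(", ", x$effects_model) else "",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$or_))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$q, x$n_snps - 1L, x$q_pval))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  }
  invisible(x)
}

# Pull aligned exposure/outcome effect columns out of a harmonized set.
hs_columns <- function(h, outcome = NULL, exposure = "exposure") {
  if (is.null(outcome)) {
    studies <- attr(h, "studies")
    if (is.null(studies)) {
      studies <- setdiff(sub("^beta_", "", grep("^beta_", names(h),
                                                value = TRUE)), exposure)
    }
    if (length(studies) == 0L) stop("no aligned study columns found")
    outcome <- studies[1]
  }
  cols <- c(paste0("beta_", exposure), paste0("se_", exposure),
            paste0("beta_", outcome), paste0("se_", outcome))
  if (!all(cols %in% names(h))) {
    stop("harmonized set lacks columns for exposure '", exposure,
         "' / outcome '", outcome, "'")
  }
  list(bx = h[[cols[1]]], sx = h[[cols[2]]],
       by = h[[cols[3]]], sy = h[[cols[4]]], snp_id = h$snp_id)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate `by/bx` with first-order delta-method
#' standard error `sy/|bx|`; the optional second-order expansion adds the
#' exposure-side term, `sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4)`.
#'
#' @param bx,sx instrument-exposure effect and its SE (`sx` needed only for
#'   the second-order SE).
#' @param by,sy instrument-outcome effect and its SE.
#' @param second_order use the second-order delta-method SE.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(bx, by, sy, sx = NULL, second_order = FALSE) {
  if (bx == 0) stop("Wald ratio undefined: instrument-exposure effect is zero")
  beta <- by / bx
  se <- sy / abs(bx)
  if (second_order) {
    if (is.null(sx)) stop("second-order Wald SE requires sx")
    se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  mr_estimate("wald", beta, se, n_snps = 1L)
}

ivw_fit <- function(bx, by, sy) {
  bhat <- by / bx
  w <- (sy / abs(bx))^-2
  beta <- sum(w * bhat) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (bhat - beta)^2)
  list(beta = beta, se_fixed = se_fixed, q = q)
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines per-SNP Wald ratios with weights `(sy/|bx|)^-2` (algebraically,
#' weighted least squares of outcome on exposure effects through the
#' origin).  Cochran's Q measures heterogeneity of the ratios; under the
#' random-effects (multiplicative) model the fixed-effects SE is inflated by
#' `max(1, sqrt(Q/(k-1)))`.  With `effects_model = "auto"` the random model
#' is used exactly when the Q p-value is below 0.05, mirroring the usual
#' "heterogeneity implies random effects" rule.
#'
#' @param h a `harmonized_set` (or anything with the aligned beta/se
#'   columns).
#' @param effects_model `"auto"`, `"fixed"` or `"random"`.
#' @param outcome which aligned study to treat as outcome (default: the
#'   first).
#' @param exposure which study supplies the exposure effects.
#' @return An `mr_estimate` with `q`, `q_pval` and the model actually used.
#' @export
mr_ivw <- function(h, effects_model = c("auto", "fixed", "random"),
                   outcome = NULL, exposure = "exposure") {
  effects_model <- match.arg(effects_model)
  d <- hs_columns(h, outcome, exposure)
  k <- length(d$bx)
  if (k < 2L) {
    stop("IVW needs at least 2 SNPs; use wald_ratio() for a single instrument")
  }
  fit <- ivw_fit(d$bx, d$by, d$sy)
  q_pval <- stats::pchisq(fit$q, df = k - 1, lower.tail = FALSE)
  model <- switch(effects_model,
                  fixed = "fixed", random = "random",
                  auto = if (q_pval < 0.05) "random" else "fixed")
  se <- if (model == "random") {
    fit$se_fixed * max(1, sqrt(fit$q / (k - 1)))
  } else {
    fit$se_fixed
  }
  mr_estimate("ivw", fit$beta, se, n_snps = k, q = fit$q, q_pval = q_pval,
              effects_model = model)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept, after orienting alleles so every exposure effect is
#' non-negative; weights are `sy^-2`.  The slope is the pleiotropy-adjusted
#' causal estimate and the intercept, with its SE and p-value, is the test
#' for directional horizontal pleiotropy.  Standard errors carry the
#' multiplicative overdispersion factor `max(1, sqrt(RSS_w/(k-2)))` and
#' p-values use the t distribution on `k - 2` df.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with method `"egger"` and intercept fields.
#' @export
mr_egger <- function(h, outcome = NULL, exposure = "exposure") {
  d <- hs_columns(h, outcome, exposure)
  k <- length(d$bx)
  if (k < 3L) stop("MR-Egger needs at least 3 SNPs")
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- d$sy^-2
  if (stats::var(bx) == 0) {
    stop("collinear instruments: all exposure effects identical after orientation")
  }
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swx2 * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  rss_w <- sum(w * resid^2)
  phi <- max(1, sqrt(rss_w / (k - 2)))
  se_slope <- sqrt(sw / det) * phi
  se_int <- sqrt(swx2 / det) * phi
  q_pval <- stats::pchisq(rss_w, df = k - 2, lower.tail = FALSE)
  est <- mr_estimate("egger", slope, se_slope, n_snps = k, df = k - 2,
                     q = rss_w, q_pval = q_pval,
                     egger_intercept = intercept,
                     egger_intercept_se = se_int,
                     egger_intercept_pval =
                       2 * stats::pt(-abs(intercept / se_int), df = k - 2))
  est
}

weighted_median_point <- function(bhat, w) {
  ord <- order(bhat)
  b <- bhat[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(x = p, y = b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-SNP Wald ratios, consistent when at least
#' half the instrument weight comes from valid instruments.  Ratios are
#' ordered and the estimate is the linear interpolation of the ratio at the
#' point where the midpoint cumulative weight (cumulative normalized weight
#' minus half the SNP's own weight) crosses one half.  The SE comes from a
#' seeded parametric bootstrap: exposure and outcome effects are redrawn
#' from normal distributions centred on the observed values with the
#' reported SEs, and the SD of the bootstrap estimates is reported.
#'
#' @inheritParams mr_ivw
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed, outcome = NULL,
                               exposure = "exposure") {
  if (n_boot <= 0) stop("n_boot must be a positive count")
  if (missing(seed)) stop("a bootstrap seed is required")
  d <- hs_columns(h, outcome, exposure)
  k <- length(d$bx)
  if (k < 3L) stop("weighted median needs at least 3 SNPs")
  w <- (d$sy / abs(d$bx))^-2
  beta <- weighted_median_point(d$by / d$bx, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, d$bx, d$sx)
    by <- stats::rnorm(k, d$by, d$sy)
    wb <- (d$sy / abs(bx))^-2
    weighted_median_point(by / bx, wb)
  }, numeric(1))
  mr_estimate("weighted_median", beta, stats::sd(boots), n_snps = k)
}

#' Run the standard univariable MR method battery
#'
#' Convenience wrapper computing IVW (with the auto fixed/random rule),
#' MR-Egger and the weighted median on one harmonized exposure-outcome set,
#' returned as a tidy table suitable for forest-plot output.
#'
#' @inheritParams mr_weighted_median
#' @param effects_model passed to [mr_ivw()].
#' @return data.frame with one row per method: `method`, `n_snps`, `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `pval`, `q`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_pval`.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed,
                           effects_model = "auto", outcome = NULL,
                           exposure = "exposure") {
  ests <- list(
    mr_ivw(h, effects_model, outcome, exposure),
    mr_egger(h, outcome, exposure),
    mr_weighted_median(h, n_boot, seed, outcome, exposure)
  )
  do.call(rbind, lapply(ests, as.data.frame.mr_estimate))
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, q = x$q, q_pval = x$q_pval,
             egger_intercept = x$egger_intercept,
             egger_intercept_pval = x$egger_intercept_pval,
             effects_model = x$effects_model,
             stringsAsFactors = FALSE)
}
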