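# Independent oracles, deliberately implemented by routes different from the
# package internals.

# IVW as weighted least squares of by on bx through the origin, via lm():
# the fixed-effects SE is the lm coefficient SE with the residual scale
# divided out.
oracle_wls_origin <- function(bx, by, sy) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[1])
  se_fixed <- unname(sm$coefficients[1, 2] / sm$sigma)
  list(beta = beta, se_fixed = se_fixed,
       q = sum((1 / sy^2) * stats::resid(fit)^2))
}

# Egger regression by explicit 2x2 normal equations on oriented data.
oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  x <- bx * flip
  y <- by * flip
  w <- 1 / sy^2
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  b <- c(sum(w * y), sum(w * x * y))
  coefs <- solve(A, b)
  resid <- y - coefs[1] - coefs[2] * x
  rss_w <- sum(w * resid^2)
  k <- length(x)
  phi <- max(1, sqrt(rss_w / (k - 2)))
  cov_unscaled <- solve(A)
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = sqrt(cov_unscaled[1, 1]) * phi,
       se_slope = sqrt(cov_unscaled[2, 2]) * phi)
}

# Weighted median by exhaustive scan over interpolation intervals.
oracle_weighted_median <- function(bhat, w) {
  ord <- order(bhat)
  b <- bhat[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  k <- length(b)
  if (p[1] >= 0.5) return(b[1])
  if (p[k] <= 0.5) return(b[k])
  for (j in seq_len(k - 1)) {
    if (p[j] <= 0.5 && 0.5 <= p[j + 1]) {
      return(b[j] + (b[j + 1] - b[j]) * (0.5 - p[j]) / (p[j + 1] - p[j]))
    }
  }
  stop("no interval found")
}

# Greedy clumping oracle working directly on an r2 matrix and positions.
oracle_clump <- function(ids, pvals, chrom, pos, r2mat, window_bp, r2_max) {
  remaining <- seq_along(ids)
  kept <- integer(0)
  while (length(remaining) > 0) {
    o <- remaining[order(pvals[remaining], ids[remaining])]
    idx <- o[1]
    kept <- c(kept, idx)
    remove <- vapply(remaining, function(j) {
      j != idx && chrom[j] == chrom[idx] &&
        abs(pos[j] - pos[idx]) <= window_bp &&
        r2mat[idx, j] >= r2_max
    }, logical(1))
    remaining <- setdiff(remaining[!remove], idx)
  }
  ids[kept]
}

# DerSimonian-Laird pooling straight from the formulas.
oracle_dl <- function(betas, ses, model = "auto") {
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - beta_fe)^2)
  m <- length(betas)
  q_p <- stats::pchisq(q, m - 1, lower.tail = FALSE)
  random <- switch(model, fixed = FALSE, random = TRUE, auto = q_p < 0.05)
  if (!random) {
    list(beta = beta_fe, se = 1 / sqrt(sum(w)), tau2 = 0, q = q, q_pval = q_p)
  } else {
    tau2 <- max(0, (q - (m - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (ses^2 + tau2)
    list(beta = sum(wr * betas) / sum(wr), se = 1 / sqrt(sum(wr)),
         tau2 = tau2, q = q, q_pval = q_p)
  }
}

# Rule-by-rule candidate screen, one pair at a time.
oracle_screen <- function(df, alpha = 0.05, presso_alpha = 0.05) {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$ivw_pval >= alpha) return("ivw not significant")
    if (sign(r$egger_beta) != sign(r$ivw_beta)) return("direction disagreement")
    if (sign(r$wm_beta) != sign(r$ivw_beta)) return("direction disagreement")
    if (r$presso_global_pval < presso_alpha) return("pleiotropy detected")
    if (r$meta_pval >= alpha) return("meta-analysis not significant")
    "pass"
  }, character(1))
}
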