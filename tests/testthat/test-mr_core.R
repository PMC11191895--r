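test_that("Wald ratio arithmetic and error behaviour", {
  est <- wald_ratio(bx = 0.5, by = 0.25, sy = 0.1)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  null_est <- wald_ratio(bx = 0.5, by = 0, sy = 0.1)
  expect_equal(null_est$beta, 0)
  expect_equal(null_est$pval, 1)
  expect_error(wald_ratio(bx = 0, by = 0.1, sy = 0.1), "zero")
  # second-order SE adds the exposure-side term, so it is strictly larger
  first <- wald_ratio(0.5, 0.25, 0.1)
  second <- wald_ratio(0.5, 0.25, 0.1, sx = 0.05, second_order = TRUE)
  expect_equal(second$se, sqrt(0.1^2 / 0.5^2 + 0.25^2 * 0.05^2 / 0.5^4))
  expect_gt(second$se, first$se)
})

test_that("IVW reduces to the Wald ratio under replication and zero Q", {
  h <- make_harmonized(bx = c(0.5, 0.5), sx = 0.01,
                       by = c(0.25, 0.25), sy = c(0.1, 0.1))
  est <- mr_ivw(h, "fixed")
  w <- wald_ratio(0.5, 0.25, 0.1)
  expect_equal(est$beta, w$beta)
  expect_equal(est$se, w$se / sqrt(2))
  # all ratios identical: Q = 0, p = 1, random SE equals fixed SE
  h2 <- make_harmonized(bx = c(0.2, 0.4, 0.5), sx = 0.01,
                        by = c(0.2, 0.4, 0.5) * 0.3, sy = 0.05)
  fixed <- mr_ivw(h2, "fixed")
  rand <- mr_ivw(h2, "random")
  expect_equal(fixed$q, 0)
  expect_equal(fixed$q_pval, 1)
  expect_equal(rand$se, fixed$se)
  expect_error(mr_ivw(make_harmonized(0.5, 0.01, 0.2, 0.1)), "wald_ratio")
})

test_that("IVW equals the WLS-through-origin oracle to 1e-10", {
  set.seed(303)
  for (rep in 1:5) {
    k <- 5
    bx <- stats::rnorm(k, 0.1, 0.05)
    by <- 0.3 * bx + stats::rnorm(k, 0, 0.02)
    sy <- stats::runif(k, 0.01, 0.05)
    h <- make_harmonized(bx, 0.01, by, sy)
    est <- mr_ivw(h, "fixed")
    want <- oracle_wls_origin(bx, by, sy)
    expect_equal(est$beta, want$beta, tolerance = 1e-10)
    expect_equal(est$se, want$se_fixed, tolerance = 1e-10)
    expect_equal(est$q, want$q, tolerance = 1e-10)
  }
})

test_that("IVW is invariant to joint sign flips and auto picks by Q", {
  set.seed(42)
  k <- 8
  bx <- stats::rnorm(k, 0.1, 0.04)
  by <- 0.3 * bx + stats::rnorm(k, 0, 0.05)
  sy <- rep(0.03, k)
  h <- make_harmonized(bx, 0.01, by, sy)
  flip <- rep(1, k); flip[c(2, 5)] <- -1
  h_flip <- make_harmonized(bx * flip, 0.01, by * flip, sy)
  e1 <- mr_ivw(h, "fixed")
  e2 <- mr_ivw(h_flip, "fixed")
  expect_equal(e1$beta, e2$beta)
  expect_equal(e1$q, e2$q)
  # auto rule: random iff q_pval < 0.05, and random SE >= fixed SE always
  auto <- mr_ivw(h, "auto")
  expect_equal(auto$effects_model,
               if (auto$q_pval < 0.05) "random" else "fixed")
  for (seed in 1:10) {
    set.seed(seed)
    byh <- 0.3 * bx + stats::rnorm(k, 0, 0.08)
    hh <- make_harmonized(bx, 0.01, byh, sy)
    expect_gte(mr_ivw(hh, "random")$se, mr_ivw(hh, "fixed")$se)
  }
})

test_that("Egger recovers exact fits and matches the normal-equation oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_harmonized(bx, 0.01, 0.5 * bx, 0.02)
  est <- mr_egger(h)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0, tolerance = 1e-12)

  # adding a constant to every outcome effect shifts only the intercept
  h2 <- make_harmonized(bx, 0.01, 0.5 * bx + 0.07, 0.02)
  est2 <- mr_egger(h2)
  expect_equal(est2$beta, est$beta, tolerance = 1e-10)
  expect_equal(est2$egger_intercept, est$egger_intercept + 0.07,
               tolerance = 1e-10)

  set.seed(99)
  k <- 10
  bx <- abs(stats::rnorm(k, 0.15, 0.05))
  by <- 0.02 + 0.4 * bx + stats::rnorm(k, 0, 0.03)
  sy <- stats::runif(k, 0.02, 0.06)
  est3 <- mr_egger(make_harmonized(bx, 0.01, by, sy))
  want <- oracle_egger(bx, by, sy)
  expect_equal(est3$beta, want$slope, tolerance = 1e-10)
  expect_equal(est3$egger_intercept, want$intercept, tolerance = 1e-10)
  expect_equal(est3$se, want$se_slope, tolerance = 1e-10)
  expect_equal(est3$egger_intercept_se, want$se_intercept, tolerance = 1e-10)

  expect_error(mr_egger(make_harmonized(rep(0.2, 4), 0.01,
                                        c(0.1, 0.2, 0.1, 0.2), 0.02)),
               "collinear")
})

test_that("weighted median handles exact cases and matches the scan oracle", {
  # equal weights, odd n: the middle ratio exactly
  h <- make_harmonized(bx = rep(1, 5), sx = 0.01,
                       by = c(0.1, 0.3, 0.2, 0.5, 0.4), sy = 0.1)
  est <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.3)

  # a dominant-weight SNP sitting at the 50% crossing gives its own ratio
  h2 <- make_harmonized(bx = rep(1, 3), sx = 0.01,
                        by = c(0.1, 0.25, 0.6),
                        sy = c(0.2, 0.2 / sqrt(3), 0.2))
  est2 <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_equal(est2$beta, 0.25)

  set.seed(1234)
  k <- 7
  bx <- stats::rnorm(k, 0.2, 0.05)
  by <- 0.3 * bx + stats::rnorm(k, 0, 0.04)
  sy <- stats::runif(k, 0.02, 0.08)
  h3 <- make_harmonized(bx, 0.01, by, sy)
  est3 <- mr_weighted_median(h3, n_boot = 50, seed = 2)
  expect_equal(est3$beta,
               oracle_weighted_median(by / bx, (sy / abs(bx))^-2))

  # identical seeds give identical bootstrap SEs; different seeds differ
  a <- mr_weighted_median(h3, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h3, n_boot = 200, seed = 7)
  c <- mr_weighted_median(h3, n_boot = 200, seed = 8)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_error(mr_weighted_median(h3, n_boot = 0, seed = 1), "positive")
})

test_that("all estimators converge to the true effect as noise vanishes", {
  # 50 valid instruments, no pleiotropy: as the per-SNP sampling errors
  # shrink, every method's mean absolute error must shrink with them
  run_scale <- function(noise) {
    set.seed(2024)
    n_rep <- 40
    res <- replicate(n_rep, {
      k <- 50
      gamma <- stats::runif(k, 0.05, 0.15)
      bx <- gamma + stats::rnorm(k, 0, noise)
      by <- 0.3 * gamma + stats::rnorm(k, 0, 2 * noise)
      h <- make_harmonized(bx, noise, by, rep(2 * noise, k))
      c(ivw = mr_ivw(h, "fixed")$beta,
        egger = mr_egger(h)$beta,
        wm = mr_weighted_median(h, n_boot = 10, seed = 1)$beta)
    })
    rowMeans(abs(res - 0.3))
  }
  coarse <- run_scale(2e-3)
  fine <- run_scale(1e-4)
  expect_true(all(fine < coarse))
  expect_true(all(fine < 1e-3))
})

test_that("mr_all_methods returns a tidy per-method table", {
  sim <- simulate_triplet(scenario_suite("single_outlier", seed = 3))
  h <- harmonize(sim$exposure, sim$outcome)
  tab <- mr_all_methods(h, n_boot = 50, seed = 4)
  expect_equal(tab$method, c("ivw", "egger", "weighted_median"))
  expect_true(all(tab$or == exp(tab$beta)))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
})
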