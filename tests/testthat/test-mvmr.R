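test_that("joint instrument sets are the de-duplicated, re-clumped union", {
  sim <- simulate_triplet(synthetic_scenario(n_snps = 40, n_instruments = 30,
                                             palindrome_frac = 0, seed = 21))
  ids <- sim$exposure$snp_id
  exp_iv <- sim$exposure[1:8, ]
  med_iv <- sim$mediator[9:13, ]
  joint <- build_joint_instruments(exp_iv, med_iv, sim$exposure,
                                   sim$mediator, sim$outcome, sim$ld)
  expect_equal(nrow(joint), 13)   # disjoint sets, no LD: plain union
  expect_setequal(joint$snp_id, ids[1:13])
  expect_true(all(c("beta_mediator", "beta_outcome") %in% names(joint)))

  # a shared SNP appears exactly once
  joint2 <- build_joint_instruments(sim$exposure[1:8, ], sim$mediator[8:12, ],
                                    sim$exposure, sim$mediator, sim$outcome,
                                    sim$ld)
  expect_equal(nrow(joint2), 12)
  expect_equal(anyDuplicated(joint2$snp_id), 0)
})

test_that("overlapping LD blocks across the two sets re-clump jointly", {
  sim <- simulate_triplet(synthetic_scenario(n_snps = 24, n_instruments = 24,
                                             ld_block_size = 4,
                                             ld_within_r2 = 0.9,
                                             palindrome_frac = 0, seed = 31))
  exp_iv <- sim$exposure[1:10, ]
  med_iv <- sim$mediator[7:16, ]
  cfg <- instrument_config(clump_r2 = 0.1)
  joint <- build_joint_instruments(exp_iv, med_iv, sim$exposure,
                                   sim$mediator, sim$outcome, sim$ld, cfg)
  # oracle: greedy clump over the pooled list ranked by min(p_x, p_m)
  ids <- sim$exposure$snp_id[1:16]
  pmin_p <- pmin(sim$exposure$pval[1:16], sim$mediator$pval[1:16])
  pos <- ld_positions(sim$ld, ids)
  k <- length(ids)
  r2mat <- outer(seq_len(k), seq_len(k),
                 Vectorize(function(i, j) ld_r2(sim$ld, ids[i], ids[j])))
  want <- oracle_clump(ids, pmin_p, pos$chrom, pos$pos, r2mat,
                       window_bp = 1e7, r2_max = 0.1)
  expect_setequal(joint$snp_id, want)
})

test_that("a SNP absent from a full table is dropped with a reason", {
  sim <- simulate_triplet(synthetic_scenario(n_snps = 20, n_instruments = 20,
                                             palindrome_frac = 0, seed = 41))
  med_missing <- sim$mediator[-1, ]   # rs1 absent from the mediator GWAS
  joint <- build_joint_instruments(sim$exposure[1:6, ], med_missing[1:5, ],
                                   sim$exposure, med_missing, sim$outcome,
                                   sim$ld)
  expect_false("rs1" %in% joint$snp_id)
  dropped <- attr(joint, "dropped")
  expect_true("rs1" %in% dropped$snp_id[dropped$reason == "missing"])
})

test_that("multivariable IVW recovers exact linear structure", {
  set.seed(55)
  k <- 30
  bx1 <- stats::rnorm(k, 0.1, 0.05)
  bx2 <- stats::rnorm(k, 0, 0.08)
  by <- 0.2 * bx1 + 0.5 * bx2
  h <- make_harmonized(bx1, 0.01, by, 0.03, bm = bx2, sm = 0.01)
  res <- mvmr_ivw(h, exposures = c("exposure", "mediator"))
  expect_equal(unname(res$betas["exposure"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(res$betas["mediator"]), 0.5, tolerance = 1e-10)
})

test_that("multivariable IVW matches the normal-equations oracle to 1e-10", {
  set.seed(56)
  k <- 30
  bx1 <- stats::rnorm(k, 0.1, 0.05)
  bx2 <- stats::rnorm(k, 0, 0.08)
  sy <- stats::runif(k, 0.02, 0.05)
  by <- 0.2 * bx1 + 0.5 * bx2 + stats::rnorm(k, 0, sy)
  h <- make_harmonized(bx1, 0.01, by, sy, bm = bx2, sm = 0.01)
  res <- mvmr_ivw(h, exposures = c("exposure", "mediator"))
  W <- diag(1 / sy^2)
  X <- cbind(bx1, bx2)
  betas <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  resid <- by - X %*% betas
  phi <- max(1, sqrt(sum((resid^2) / sy^2) / (k - 2)))
  ses <- sqrt(diag(solve(t(X) %*% W %*% X))) * phi
  expect_equal(unname(res$betas), unname(drop(betas)), tolerance = 1e-10)
  expect_equal(unname(res$ses), unname(ses), tolerance = 1e-10)
})

test_that("column order permutes results and degenerate designs error", {
  set.seed(57)
  k <- 20
  bx1 <- stats::rnorm(k, 0.1, 0.05)
  bx2 <- stats::rnorm(k, 0, 0.08)
  by <- 0.2 * bx1 + 0.5 * bx2 + stats::rnorm(k, 0, 0.02)
  h <- make_harmonized(bx1, 0.01, by, 0.03, bm = bx2, sm = 0.01)
  a <- mvmr_ivw(h, exposures = c("exposure", "mediator"))
  b <- mvmr_ivw(h, exposures = c("mediator", "exposure"))
  expect_equal(a$betas[["exposure"]], b$betas[["exposure"]])
  expect_equal(a$betas[["mediator"]], b$betas[["mediator"]])
  expect_equal(rev(a$exposures), b$exposures)

  # perfectly collinear exposure/mediator effects
  h_col <- make_harmonized(bx1, 0.01, by, 0.03, bm = 2 * bx1, sm = 0.01)
  expect_error(mvmr_ivw(h_col, exposures = c("exposure", "mediator")),
               "collinear")
  # more exposures than instruments
  expect_error(mvmr_ivw(h[1:2, ], exposures = c("exposure", "mediator")),
               "instruments")
})

test_that("an all-zero mediator column reduces to the univariable fit", {
  set.seed(58)
  k <- 15
  bx <- stats::rnorm(k, 0.1, 0.05)
  sy <- rep(0.03, k)
  by <- 0.3 * bx + stats::rnorm(k, 0, sy)
  h <- make_harmonized(bx, 0.01, by, sy, bm = rep(0, k), sm = 0.01)
  res <- mvmr_ivw(h, exposures = c("exposure", "mediator"))
  uni <- mr_ivw(make_harmonized(bx, 0.01, by, sy), "fixed")
  expect_equal(unname(res$betas["exposure"]), uni$beta, tolerance = 1e-12)
  expect_true(is.na(res$betas["mediator"]))
})

test_that("MVMR recovers the adjusted paths on the structural model", {
  # moderate replicate count; the acceptance suite runs the full version
  n_rep <- 60
  res <- sapply(seq_len(n_rep), function(s) {
    sim <- simulate_triplet(scenario_suite("strong_mediation", seed = s + 500))
    h <- harmonize(sim$exposure, list(mediator = sim$mediator,
                                      outcome = sim$outcome))
    mv <- mvmr_ivw(h, exposures = c("exposure", "mediator"))
    c(mv$betas[["mediator"]], mv$betas[["exposure"]])
  })
  mcse <- apply(res, 1, stats::sd) / sqrt(n_rep)
  expect_lt(abs(mean(res[1, ]) - 0.4), 2 * mcse[1])
  expect_lt(abs(mean(res[2, ]) - 0.2), 2 * mcse[2])
})
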