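test_that("well-formed tables are read completely and match a hand parse", {
  tab <- data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    ea = c("a", "C", "t"),        # lowercase must be uppercased
    oa = c("g", "T", "c"),
    frq = c(0.21, 0.45, 0.07),
    b = c(0.05, -0.12, 0.30),
    stderr = c(0.01, 0.03, 0.08),
    p = c(5.7e-7, 6.3e-5, 1.8e-4),
    N = c(12000, 12000, 11950)
  )
  path <- write_fixture_tsv(tab)
  rec <- read_sumstats(path, column_map = c(
    snp_id = "rsid", effect_allele = "ea", other_allele = "oa",
    eaf = "frq", beta = "b", se = "stderr", pval = "p", n = "N"))
  expect_s3_class(rec, "sumstats")
  expect_equal(nrow(rec), 3)
  expect_equal(nrow(attr(rec, "rejects")), 0)
  expect_equal(rec$effect_allele, c("A", "C", "T"))
  expect_equal(rec$other_allele, c("G", "T", "C"))
  # field-by-field against the hand-parsed source
  expect_equal(rec$snp_id, tab$rsid)
  expect_equal(rec$eaf, tab$frq)
  expect_equal(rec$beta, tab$b)
  expect_equal(rec$se, tab$stderr)
  expect_equal(rec$pval, tab$p)
  expect_equal(rec$n, as.numeric(tab$N))
})

test_that("invariant violations are rejected row-by-row with reasons", {
  tab <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "AT", "A", "A"),
    other_allele = c("G", "G", "T", "A", "G"),
    eaf = c(0.2, 0.2, 0.2, 0.2, 0.2),
    beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
    se = c(0.02, 0, 0.02, 0.02, 0.02),
    pval = c(1e-6, 1e-6, 1e-6, 1e-6, 1.5),
    n = 1000
  )
  rec <- read_sumstats(write_fixture_tsv(tab))
  rejects <- attr(rec, "rejects")
  expect_equal(rec$snp_id, "rs1")
  expect_setequal(rejects$snp_id, c("rs2", "rs3", "rs4", "rs5"))
  expect_equal(rejects$reason[rejects$snp_id == "rs2"], "nonpositive se")
  expect_equal(rejects$reason[rejects$snp_id == "rs3"],
               "allele not a single A/C/G/T base")
  expect_equal(rejects$reason[rejects$snp_id == "rs4"],
               "effect and other allele identical")
  expect_equal(rejects$reason[rejects$snp_id == "rs5"],
               "pval outside (0,1]")
  # missing mapped column is a configuration error
  expect_error(read_sumstats(write_fixture_tsv(tab[, -6])),
               "required column")
})

test_that("sumstats tables round-trip through write_sumstats", {
  x <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, -0.2),
                     se = c(0.02, 0.05))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path)
  expect_equal(as.data.frame(y), as.data.frame(x), ignore_attr = TRUE)
})

test_that("allele flips are harmonized with beta sign and eaf reversal", {
  expo <- make_sumstats("rs1", "A", "G", beta = 0.1, eaf = 0.2)
  outc <- make_sumstats("rs1", "G", "A", beta = 0.2, eaf = 0.8)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h), 1)
  expect_equal(h$beta_outcome, -0.2)
  expect_equal(h$eaf_outcome, 0.2)

  # strand (complement) flip with matching orientation is kept as-is
  outc2 <- make_sumstats("rs1", "T", "C", beta = 0.2, eaf = 0.2)
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$beta_outcome, 0.2)

  # irreconcilable alleles are dropped, never silently kept
  outc3 <- make_sumstats("rs1", "A", "C", beta = 0.2)
  h3 <- harmonize(expo, outc3)
  expect_equal(nrow(h3), 0)
  expect_equal(attr(h3, "dropped")$reason, "allele mismatch")
})

test_that("palindromic SNPs are frequency-resolved or dropped as ambiguous", {
  # maximal ambiguity: eaf exactly 0.5 on both sides
  expo <- make_sumstats("rs1", "A", "T", eaf = 0.5)
  outc <- make_sumstats("rs1", "A", "T", eaf = 0.5, beta = 0.2)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped")$reason, "ambiguous palindrome")

  # C/G with exposure eaf 0.10 and outcome eaf 0.88 under the same stated
  # effect allele: the frequencies imply the outcome is reported for the
  # opposite strand's allele, so the beta flips. Enumerating the four
  # strand/designation configurations, only the swapped one is consistent
  # with both frequencies (0.10 vs 1-0.88 = 0.12).
  expo2 <- make_sumstats("rs2", "C", "G", eaf = 0.10, beta = 0.1)
  outc2 <- make_sumstats("rs2", "C", "G", eaf = 0.88, beta = 0.3)
  h2 <- harmonize(expo2, outc2)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$beta_outcome, -0.3)
  expect_equal(h2$eaf_outcome, 0.12)

  # concordant frequencies on the same side: kept unflipped
  outc3 <- make_sumstats("rs2", "C", "G", eaf = 0.12, beta = 0.3)
  expect_equal(harmonize(expo2, outc3)$beta_outcome, 0.3)

  # palindromic SNP without eaf cannot be resolved
  expo4 <- make_sumstats("rs4", "A", "T", eaf = NA)
  outc4 <- make_sumstats("rs4", "A", "T", eaf = 0.2)
  h4 <- harmonize(expo4, outc4)
  expect_equal(attr(h4, "dropped")$reason, "ambiguous palindrome")

  # frequency inside the ambiguity window on either side drops the SNP
  expo5 <- make_sumstats("rs5", "A", "T", eaf = 0.44)
  outc5 <- make_sumstats("rs5", "A", "T", eaf = 0.2)
  expect_equal(attr(harmonize(expo5, outc5), "dropped")$reason,
               "ambiguous palindrome")
})

test_that("every input SNP is accounted for in retained or dropped", {
  for (seed in 1:5) {
    sim <- simulate_triplet(synthetic_scenario(n_snps = 40,
                                               n_instruments = 20,
                                               palindrome_frac = 0.3,
                                               seed = seed))
    # knock some SNPs out of the outcome to create "missing" drops
    outc <- sim$outcome[-seq_len(5), ]
    h <- harmonize(sim$exposure, list(outcome = outc))
    dropped <- attr(h, "dropped")
    expect_equal(sort(c(h$snp_id, dropped$snp_id)),
                 sort(sim$exposure$snp_id))
    expect_equal(anyDuplicated(c(h$snp_id, dropped$snp_id)), 0)
  }
})

test_that("harmonization is idempotent and orientation-invariant", {
  sim <- simulate_triplet(synthetic_scenario(n_snps = 30,
                                             n_instruments = 20,
                                             palindrome_frac = 0.3,
                                             seed = 11))
  h1 <- harmonize(sim$exposure, list(outcome = sim$outcome))
  # rebuild sumstats from the harmonized output and harmonize again
  expo2 <- sumstats(h1$snp_id, h1$effect_allele, h1$other_allele,
                    beta = h1$beta_exposure, se = h1$se_exposure,
                    pval = h1$pval_exposure, eaf = h1$eaf_exposure)
  outc2 <- sumstats(h1$snp_id, h1$effect_allele, h1$other_allele,
                    beta = h1$beta_outcome, se = h1$se_outcome,
                    pval = h1$pval_outcome, eaf = h1$eaf_outcome)
  h2 <- harmonize(expo2, outc2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  expect_equal(nrow(attr(h2, "dropped")), 0)

  # flipping every outcome record's alleles, beta and eaf before
  # harmonization must give the identical harmonized set
  flipped <- sim$outcome
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h3 <- harmonize(sim$exposure, list(outcome = flipped))
  expect_equal(h3$beta_outcome, h1$beta_outcome)
  expect_equal(h3$snp_id, h1$snp_id)
})

test_that("LD reference lookups are symmetric with identity and defaults", {
  ld <- ld_reference(
    data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs3"),
               r2 = c(0.9, 0.4)),
    data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = 1,
               pos = c(100, 200, 300)))
  expect_equal(ld_r2(ld, "rs1", "rs2"), 0.9)
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.9)
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)
  expect_equal(ld_r2(ld, "rs1", "rs3"), 0)
  expect_error(ld_positions(ld, "rs99"), "rs99")
})
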