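# Deterministic sub-seed per draw component, so adding a component never
# shifts another component's stream.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Define a synthetic GWAS summary-statistics scenario
#'
#' Parameterizes the generative structural model: a set of SNPs, a subset
#' acting as instruments with per-SNP exposure effects
#' `gamma_j ~ N(0, gamma_sd)`, an exposure-to-mediator path `theta1`, a
#' mediator-to-outcome path `theta4`, and a direct exposure-to-outcome path
#' `theta5`, so each instrument's true outcome effect is
#' `(theta5 + theta4 * theta1) * gamma_j` plus any planted pleiotropy.  A
#' fraction of instruments can carry direct-outcome pleiotropic effects
#' (balanced, mean-zero `N(0, pleiotropy_sd)`, or directional, half-normal
#' `|N(0, pleiotropy_sd)|`), a fraction of SNPs are palindromic (A/T or
#' C/G, with frequencies drawn outside the ambiguity window so they remain
#' resolvable), LD comes in blocks with a common within-block r-squared,
#' and observed effects are the true effects plus normal sampling noise
#' with the configured per-study SEs.  The implied true mediation
#' proportion is `theta1*theta4 / (theta1*theta4 + theta5)`.
#'
#' @param n_snps total SNPs per table.
#' @param n_instruments how many have nonzero exposure effects.
#' @param n_mediator_instruments how many SNPs act on the mediator directly
#'   (protein-QTL-like instruments, disjoint from the exposure's); these
#'   give multivariable MR the mediator-specific variation it needs to
#'   separate the adjusted paths.
#' @param kappa_sd SD of the mediator instruments' true mediator effects.
#' @param gamma_sd SD of per-SNP true exposure effects.
#' @param theta1,theta4,theta5 true structural effects (log-odds scale for
#'   the binary outcome, so OR = exp(beta) downstream).
#' @param pleiotropy_frac fraction of instruments with direct-outcome
#'   effects.
#' @param pleiotropy_sd SD of those effects.
#' @param balanced_pleiotropy mean-zero (`TRUE`) vs directional (`FALSE`).
#' @param mediator_pleiotropy_sd SD of instrument-to-mediator effects not
#'   running through the exposure (0 = none).
#' @param se_x,se_m,se_y sampling SE per study (scalar or per-SNP vector).
#' @param palindrome_frac fraction of palindromic SNPs.
#' @param ld_block_size SNPs per LD block (1 = independent instruments).
#' @param ld_within_r2 r-squared between SNPs in the same block.
#' @param n_outliers number of planted single-SNP outcome outliers.
#' @param outlier_shift outlier shift in units of the outcome SE.
#' @param n_x,n_m,n_y GWAS sample sizes recorded in the tables.
#' @param snp_prefix prefix for generated SNP identifiers.
#' @param seed integer seed (mandatory; drives documented per-component
#'   sub-streams).
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_snps = 60, n_instruments = 30,
                               n_mediator_instruments = 0,
                               kappa_sd = 0.08, gamma_sd = 0.08,
                               theta1 = 0, theta4 = 0, theta5 = 0,
                               pleiotropy_frac = 0, pleiotropy_sd = 0,
                               balanced_pleiotropy = TRUE,
                               mediator_pleiotropy_sd = 0,
                               se_x = 0.01, se_m = 0.02, se_y = 0.03,
                               palindrome_frac = 0.1,
                               ld_block_size = 1, ld_within_r2 = 0.8,
                               n_outliers = 0, outlier_shift = 10,
                               n_x = 18000, n_m = 15000, n_y = 25000,
                               snp_prefix = "rs", seed) {
  if (missing(seed)) stop("a scenario seed is required")
  if (n_instruments + n_mediator_instruments > n_snps) {
    stop("instrument counts cannot exceed n_snps")
  }
  stopifnot(pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            palindrome_frac >= 0, palindrome_frac <= 1,
            gamma_sd > 0, kappa_sd > 0,
            all(se_x > 0), all(se_m > 0), all(se_y > 0),
            ld_block_size >= 1, ld_within_r2 >= 0, ld_within_r2 <= 1)
  scn <- list(n_snps = n_snps, n_instruments = n_instruments,
              n_mediator_instruments = n_mediator_instruments,
              kappa_sd = kappa_sd,
              gamma_sd = gamma_sd, theta1 = theta1, theta4 = theta4,
              theta5 = theta5, pleiotropy_frac = pleiotropy_frac,
              pleiotropy_sd = pleiotropy_sd,
              balanced_pleiotropy = balanced_pleiotropy,
              mediator_pleiotropy_sd = mediator_pleiotropy_sd,
              se_x = se_x, se_m = se_m, se_y = se_y,
              palindrome_frac = palindrome_frac,
              ld_block_size = ld_block_size, ld_within_r2 = ld_within_r2,
              n_outliers = n_outliers, outlier_shift = outlier_shift,
              n_x = n_x, n_m = n_m, n_y = n_y,
              snp_prefix = snp_prefix, seed = as.integer(seed))
  class(scn) <- "synthetic_scenario"
  scn
}

NONPAL_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)

#' Simulate a linked exposure/mediator/outcome summary-statistics triplet
#'
#' Draws one realization of the scenario's structural model and returns the
#' three GWAS summary-statistics tables (sharing SNP ids, alleles and
#' frequencies), the block LD reference, and the generative ground truth.
#' Fully reproducible from the scenario seed.
#'
#' @param scn a [synthetic_scenario()].
#' @return A list of class `mr_simulation` with elements `exposure`,
#'   `mediator`, `outcome` (`sumstats` tables), `ld` (an `ld_reference`)
#'   and `truth` (a list holding the per-SNP true effects, the instrument,
#'   pleiotropic and outlier SNP ids, and the true `beta1`..`beta5`,
#'   `indirect`, `total` and `proportion`).
#' @export
simulate_triplet <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  k <- scn$n_snps
  ids <- paste0(scn$snp_prefix, seq_len(k))
  se_x <- rep_len(scn$se_x, k)
  se_m <- rep_len(scn$se_m, k)
  se_y <- rep_len(scn$se_y, k)

  # --- genotype layer: alleles, frequencies, positions, LD blocks
  set.seed(sub_seed(scn$seed, "genotype"))
  n_pal <- round(scn$palindrome_frac * k)
  pal <- c(rep(TRUE, n_pal), rep(FALSE, k - n_pal))
  alleles <- matrix("", k, 2)
  pick <- function(m) m[sample.int(nrow(m), 1), ]
  for (i in seq_len(k)) {
    alleles[i, ] <- if (pal[i]) pick(PAL_PAIRS) else pick(NONPAL_PAIRS)
  }
  eaf <- stats::runif(k, 0.05, 0.95)
  # keep palindromes outside the ambiguity window so harmonization can
  # resolve them; ambiguous palindromes are planted explicitly in fixtures
  low <- stats::runif(k, 0.05, 0.40)
  eaf[pal] <- ifelse(stats::runif(sum(pal)) < 0.5, low[pal], 1 - low[pal])
  n_blocks <- ceiling(k / scn$ld_block_size)
  block <- rep(seq_len(n_blocks), each = scn$ld_block_size)[seq_len(k)]
  chrom <- ((block - 1) %% 22) + 1
  block_on_chrom <- (block - 1) %/% 22
  pos <- block_on_chrom * 25e6 + (seq_len(k) - (block - 1) * scn$ld_block_size) * 10000
  positions <- data.frame(snp_id = ids, chrom = chrom, pos = pos)
  pair_list <- list()
  if (scn$ld_block_size > 1) {
    for (b in unique(block)) {
      members <- ids[block == b]
      if (length(members) > 1) {
        cmb <- utils::combn(members, 2)
        pair_list[[length(pair_list) + 1]] <-
          data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                     r2 = scn$ld_within_r2)
      }
    }
  }
  pairs <- if (length(pair_list) > 0) do.call(rbind, pair_list) else
    data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0))
  ld <- ld_reference(pairs, positions)

  # --- structural layer: true per-SNP effects
  set.seed(sub_seed(scn$seed, "effects"))
  instrument <- seq_len(k) <= scn$n_instruments
  med_instrument <- seq_len(k) > scn$n_instruments &
    seq_len(k) <= scn$n_instruments + scn$n_mediator_instruments
  gamma <- ifelse(instrument, stats::rnorm(k, 0, scn$gamma_sd), 0)
  kappa <- ifelse(med_instrument, stats::rnorm(k, 0, scn$kappa_sd), 0)
  eta <- if (scn$mediator_pleiotropy_sd > 0) {
    ifelse(instrument, stats::rnorm(k, 0, scn$mediator_pleiotropy_sd), 0)
  } else rep(0, k)
  n_pleio <- round(scn$pleiotropy_frac * scn$n_instruments)
  pleio_idx <- if (n_pleio > 0) {
    sample(which(instrument), n_pleio)
  } else integer(0)
  delta <- rep(0, k)
  if (n_pleio > 0) {
    raw <- stats::rnorm(n_pleio, 0, scn$pleiotropy_sd)
    delta[pleio_idx] <- if (scn$balanced_pleiotropy) raw else abs(raw)
  }
  true_x <- gamma
  true_m <- scn$theta1 * gamma + kappa + eta
  true_y <- (scn$theta5 + scn$theta4 * scn$theta1) * gamma +
    scn$theta4 * (kappa + eta) + delta

  # --- sampling layer: observed betas per study
  draw <- function(label, true, se) {
    set.seed(sub_seed(scn$seed, label))
    true + stats::rnorm(k, 0, se)
  }
  bx <- draw("exposure_noise", true_x, se_x)
  bm <- draw("mediator_noise", true_m, se_m)
  by <- draw("outcome_noise", true_y, se_y)
  outlier_idx <- integer(0)
  if (scn$n_outliers > 0) {
    # plant outliers on the strongest instruments so they both carry IVW
    # weight (distorting the raw estimate) and stand out as residuals
    inst_idx <- which(instrument)
    outlier_idx <- inst_idx[order(-abs(gamma[inst_idx]))][seq_len(scn$n_outliers)]
    by[outlier_idx] <- by[outlier_idx] + scn$outlier_shift * se_y[outlier_idx]
  }

  tab <- function(beta, se, n) {
    # two-sided normal p, floored so extreme associations stay in (0, 1]
    pval <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
    sumstats(snp_id = ids, effect_allele = alleles[, 1],
             other_allele = alleles[, 2], beta = beta, se = se,
             pval = pval, eaf = eaf, n = n)
  }
  total <- scn$theta1 * scn$theta4 + scn$theta5
  truth <- list(
    per_snp = data.frame(snp_id = ids, gamma = gamma, kappa = kappa,
                         eta = eta, delta = delta, true_x = true_x,
                         true_m = true_m, true_y = true_y),
    instruments = ids[instrument],
    mediator_instruments = ids[med_instrument],
    pleiotropic = ids[pleio_idx],
    outliers = ids[outlier_idx],
    beta1 = scn$theta1, beta2 = scn$theta4,
    beta3 = total, beta4 = scn$theta4, beta5 = scn$theta5,
    indirect = scn$theta1 * scn$theta4, total = total,
    proportion = if (total != 0) scn$theta1 * scn$theta4 / total else
      NA_real_
  )
  structure(list(exposure = tab(bx, se_x, scn$n_x),
                 mediator = tab(bm, se_m, scn$n_m),
                 outcome = tab(by, se_y, scn$n_y),
                 ld = ld, truth = truth, scenario = scn),
            class = "mr_simulation")
}

#' Redraw the outcome table of a simulation (replication dataset)
#'
#' Generates a second, independent outcome GWAS for the same SNPs: new
#' sampling noise under a fresh seed, optionally with the direct effect
#' shifted by `theta5_shift` to emulate between-study heterogeneity in a
#' replication cohort.
#'
#' @param sim an `mr_simulation`.
#' @param seed seed for the replication draw.
#' @param theta5_shift added to the direct exposure-outcome effect for this
#'   study only.
#' @param se_y sampling SE for the replication study (defaults to the
#'   original scenario's).
#' @return A `sumstats` table aligned with `sim$outcome`.
#' @export
replicate_outcome <- function(sim, seed, theta5_shift = 0, se_y = NULL) {
  scn <- sim$scenario
  k <- scn$n_snps
  if (is.null(se_y)) se_y <- scn$se_y
  se_y <- rep_len(se_y, k)
  true_y <- sim$truth$per_snp$true_y +
    theta5_shift * sim$truth$per_snp$gamma
  set.seed(sub_seed(seed, "replication_noise"))
  by <- true_y + stats::rnorm(k, 0, se_y)
  sumstats(snp_id = sim$outcome$snp_id,
           effect_allele = sim$outcome$effect_allele,
           other_allele = sim$outcome$other_allele,
           beta = by, se = se_y,
           pval = pmax(2 * stats::pnorm(-abs(by / se_y)), 1e-300),
           eaf = sim$outcome$eaf, n = scn$n_y)
}

#' Named study-condition scenarios
#'
#' A small library of generative conditions exercising each pipeline stage:
#' \describe{
#'   \item{null}{no causal paths anywhere; for type-I-error calibration.}
#'   \item{strong_mediation}{`theta1 = 0.5`, `theta4 = 0.4`,
#'     `theta5 = 0.2`; true proportion mediated 0.5, 100 instruments.}
#'   \item{weak_mediation}{`theta1 = -0.11`, `theta4 = -0.17`,
#'     `theta5 = 0.22`; true proportion about 0.078, echoing a realistic
#'     single-digit mediation share.}
#'   \item{directional_pleiotropy}{half of the instruments carry
#'     directional (half-normal) direct-outcome effects, so the Egger
#'     intercept is nonzero.}
#'   \item{single_outlier}{a homogeneous effect (`theta5 = 0.3`, 20
#'     instruments) with one SNP's outcome effect shifted by 10 outcome
#'     SEs; for outlier detection.}
#'   \item{heterogeneous_replication}{a real effect whose replication
#'     dataset should be drawn with a shifted direct effect (see
#'     `theta5_shift` in [replicate_outcome()]); for random-effects
#'     meta-analysis.}
#' }
#'
#' @param name a scenario name, or `NULL` for the whole named list.
#' @param seed seed passed into the scenario(s).
#' @return A `synthetic_scenario`, or a named list of them.
#' @export
scenario_suite <- function(name = NULL, seed = 1L) {
  suite <- list(
    null = synthetic_scenario(n_snps = 30, n_instruments = 30,
                              palindrome_frac = 0, seed = seed),
    strong_mediation = synthetic_scenario(
      n_snps = 150, n_instruments = 100, n_mediator_instruments = 50,
      theta1 = 0.5, theta4 = 0.4, theta5 = 0.2, palindrome_frac = 0,
      gamma_sd = 0.1, kappa_sd = 0.1, se_x = 0.005, se_m = 0.005,
      seed = seed),
    weak_mediation = synthetic_scenario(
      n_snps = 150, n_instruments = 100, n_mediator_instruments = 50,
      theta1 = -0.11, theta4 = -0.17, theta5 = 0.22, palindrome_frac = 0,
      gamma_sd = 0.05, kappa_sd = 0.1, se_x = 0.005, se_m = 0.005,
      seed = seed),
    directional_pleiotropy = synthetic_scenario(
      n_snps = 50, n_instruments = 50, theta5 = 0.2,
      pleiotropy_frac = 0.5, pleiotropy_sd = 0.05,
      balanced_pleiotropy = FALSE, palindrome_frac = 0, seed = seed),
    single_outlier = synthetic_scenario(
      n_snps = 20, n_instruments = 20, theta5 = 0.3, n_outliers = 1,
      outlier_shift = 10, palindrome_frac = 0, seed = seed),
    heterogeneous_replication = synthetic_scenario(
      n_snps = 40, n_instruments = 40, theta5 = 0.3,
      palindrome_frac = 0, seed = seed)
  )
  if (is.null(name)) return(suite)
  if (!name %in% names(suite)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(suite), collapse = ", "))
  }
  suite[[name]]
}

#' Write a simulation to tab-separated files
#'
#' Writes `exposure.tsv`, `mediator.tsv`, `outcome.tsv`, `ld.tsv`,
#' `positions.tsv` and `truth.json` (the latter only when the jsonlite
#' package is available) under `dir`.
#'
#' @param sim an `mr_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  ldkeys <- strsplit(names(sim$ld$r2), "\r", fixed = TRUE)
  ldtab <- data.frame(snp_a = vapply(ldkeys, `[`, "", 1),
                      snp_b = vapply(ldkeys, `[`, "", 2),
                      r2 = unname(sim$ld$r2))
  utils::write.table(ldtab, file.path(dir, "ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ld$positions, file.path(dir, "positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
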