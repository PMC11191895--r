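#' Construct a validated GWAS summary-statistics table
#'
#' A summary-statistics table holds one row per SNP with its association to a
#' single trait: identifier, effect allele, other allele, effect-allele
#' frequency, effect size (log-odds for binary traits), standard error,
#' two-sided p-value and sample size.  All downstream MR machinery consumes
#' this representation.
#'
#' @param snp_id character vector of SNP identifiers (rsIDs or synthetic IDs).
#' @param effect_allele,other_allele single-base alleles (A/C/G/T); lowercase
#'   input is uppercased.
#' @param beta numeric per-allele effect on the trait.
#' @param se positive standard error of `beta`.
#' @param pval two-sided p-value in (0, 1].
#' @param eaf optional effect-allele frequency in \[0, 1\]; required for
#'   palindromic-SNP strand resolution during harmonization.
#' @param n optional per-SNP sample size.
#' @return A `data.frame` of class `sumstats` with one validated row per SNP.
#' @seealso [read_sumstats()], [validate_sumstats()], [harmonize()]
#' @export
sumstats <- function(snp_id, effect_allele, other_allele, beta, se, pval,
                     eaf = NA_real_, n = NA_real_) {
  df <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pval = as.numeric(pval),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  v <- validate_sumstats(df)
  if (nrow(v$rejects) > 0L) {
    stop("invalid summary-statistics rows: ",
         paste(sprintf("row %d (%s): %s", v$rejects$row, v$rejects$snp_id,
                       v$rejects$reason), collapse = "; "))
  }
  structure(v$records, class = c("sumstats", "data.frame"))
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate summary-statistics rows against the record invariants
#'
#' Checks each row for: single-base A/C/G/T alleles (indels and multi-allelic
#' records are rejected), distinct effect/other alleles, `se > 0`,
#' `pval` in (0, 1], `eaf` in \[0, 1\] when present, and parseable numerics.
#'
#' @param df a data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @return A list with `records` (the passing rows, alleles uppercased) and
#'   `rejects` (a data.frame of `row`, `snp_id`, `reason` for each failure).
#' @export
validate_sumstats <- function(df) {
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  reasons <- character(nrow(df))
  bad_allele <- !(df$effect_allele %in% BASES) | !(df$other_allele %in% BASES)
  reasons[bad_allele] <- "allele not a single A/C/G/T base"
  same <- !bad_allele & df$effect_allele == df$other_allele
  reasons[same] <- "effect and other allele identical"
  bad_beta <- reasons == "" & (!is.finite(df$beta))
  reasons[bad_beta] <- "unparseable beta"
  bad_se <- reasons == "" & (!is.finite(df$se) | df$se <= 0)
  reasons[bad_se] <- "nonpositive se"
  bad_p <- reasons == "" & (!is.finite(df$pval) | df$pval <= 0 | df$pval > 1)
  reasons[bad_p] <- "pval outside (0,1]"
  bad_eaf <- reasons == "" & !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  reasons[bad_eaf] <- "eaf outside [0,1]"
  keep <- reasons == ""
  rejects <- data.frame(
    row = which(!keep),
    snp_id = df$snp_id[!keep],
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  records <- df[keep, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("sumstats", "data.frame")
  list(records = records, rejects = rejects)
}

#' Read a GWAS summary-statistics table from a delimited file
#'
#' Reads a tab-separated table (one header row, UTF-8, `"."` or empty cells
#' as missing), renames columns through `column_map`, and validates every row.
#' Rows violating the record invariants are dropped and reported (with their
#' 1-based data row numbers) in the `rejects` attribute; a missing mapped
#' column is a configuration error.
#'
#' @param path path to the file.
#' @param column_map named character vector mapping standard field names
#'   (`snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`) to the file's column names.  Fields absent from the map are taken
#'   to have their standard name; `eaf` and `n` are optional and filled with
#'   `NA` when the file lacks them.
#' @param sep field separator, tab by default.
#' @return A `sumstats` data.frame; attribute `rejects` holds the rejected
#'   rows with reasons.
#' @export
read_sumstats <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c(".", ""),
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  fields <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta",
              "se", "pval", "n")
  map <- stats::setNames(fields, fields)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), fields)
    if (length(unknown) > 0L) {
      stop("column_map names not recognised: ", paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- map[required][!(map[required] %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  get_col <- function(field) {
    if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NA_character_
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    snp_id = as.character(get_col("snp_id")),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    pval = num(get_col("pval")),
    n = num(get_col("n")),
    stringsAsFactors = FALSE
  )
  v <- validate_sumstats(df)
  structure(v$records, rejects = v$rejects,
            class = c("sumstats", "data.frame"))
}

#' Write a summary-statistics table to a tab-separated file
#'
#' @param x a `sumstats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Build an LD reference from pairwise r-squared and position tables
#'
#' The LD reference provides a symmetric lookup of pairwise r-squared values
#' (absent pairs default to 0, a SNP with itself to 1) plus 1-based genomic
#' positions used by the clumping window.
#'
#' @param pairs a data.frame with columns `snp_a`, `snp_b`, `r2` (long
#'   format; each unordered pair listed at least once).
#' @param positions a data.frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based base-pair position).
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(pairs, positions) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)),
            all(c("snp_id", "chrom", "pos") %in% names(positions)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    stop("r2 values must lie in [0, 1]")
  }
  if (anyDuplicated(positions$snp_id)) stop("duplicated snp_id in positions")
  a <- as.character(pairs$snp_a)
  b <- as.character(pairs$snp_b)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  r2 <- stats::setNames(as.numeric(pairs$r2), key)
  r2 <- r2[!duplicated(names(r2))]
  pos <- positions[, c("snp_id", "chrom", "pos")]
  pos$snp_id <- as.character(pos$snp_id)
  structure(list(r2 = r2, positions = pos), class = "ld_reference")
}

#' Read an LD reference from tab-separated pair and position files
#'
#' @param ld_path long-format table with columns `snp_a`, `snp_b`, `r2`.
#' @param positions_path table with columns `snp_id`, `chrom`, `pos`.
#' @return An `ld_reference` object.
#' @export
read_ld_reference <- function(ld_path, positions_path) {
  pairs <- utils::read.table(ld_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  pos <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ld_reference(pairs, pos)
}

#' Look up pairwise r-squared values in an LD reference
#'
#' Vectorized over pairs; `ld_r2(ld, x, x)` is 1 and pairs absent from the
#' reference (e.g. beyond the LD window) are 0.
#'
#' @param ld an `ld_reference`.
#' @param a,b character vectors of SNP ids (recycled to a common length).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  a <- as.character(a)
  b <- as.character(b)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- unname(ld$r2[key])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' Genomic positions of SNPs in an LD reference
#'
#' @param ld an `ld_reference`.
#' @param snp_ids SNP identifiers to look up.
#' @return data.frame with `snp_id`, `chrom`, `pos`; an unknown SNP raises an
#'   error naming it.
#' @export
ld_positions <- function(ld, snp_ids) {
  idx <- match(as.character(snp_ids), ld$positions$snp_id)
  if (anyNA(idx)) {
    stop("no position in LD reference for SNP(s): ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  }
  out <- ld$positions[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

# Align one study's records to the exposure's allele orientation.
# Returns per-SNP action: "keep", "flip", or a drop reason.
align_alleles <- function(e1, e2, eaf_e, s1, s2, eaf_s, beta_s,
                          palindrome_maf_limit) {
  k <- length(e1)
  action <- character(k)
  for (i in seq_len(k)) {
    if (is_palindromic(e1[i], e2[i])) {
      # For A/T and C/G pairs a strand flip is indistinguishable from an
      # allele swap; nominal labels only say whether the stated effect
      # alleles agree, and frequency must settle the strand.
      if (!setequal(c(s1[i], s2[i]), c(e1[i], e2[i]))) {
        action[i] <- "allele mismatch"
        next
      }
      fe <- eaf_e[i]
      fs <- if (s1[i] == e1[i]) eaf_s[i] else 1 - eaf_s[i]
      if (is.na(fe) || is.na(fs) ||
          (fe >= palindrome_maf_limit && fe <= 1 - palindrome_maf_limit) ||
          (fs >= palindrome_maf_limit && fs <= 1 - palindrome_maf_limit)) {
        action[i] <- "ambiguous palindrome"
        next
      }
      nominal <- if (s1[i] == e1[i]) "keep" else "flip"
      # discordant frequency sides: the stated alleles name opposite strands
      if ((fe < 0.5) != (fs < 0.5)) {
        nominal <- if (nominal == "keep") "flip" else "keep"
      }
      action[i] <- nominal
    } else {
      if (s1[i] == e1[i] && s2[i] == e2[i]) {
        action[i] <- "keep"
      } else if (s1[i] == e2[i] && s2[i] == e1[i]) {
        action[i] <- "flip"
      } else if (COMPLEMENT[s1[i]] == e1[i] && COMPLEMENT[s2[i]] == e2[i]) {
        action[i] <- "keep"
      } else if (COMPLEMENT[s1[i]] == e2[i] && COMPLEMENT[s2[i]] == e1[i]) {
        action[i] <- "flip"
      } else {
        action[i] <- "allele mismatch"
      }
    }
  }
  action
}

#' Harmonize effect alleles across summary-statistics tables
#'
#' Aligns one or more studies (outcome, mediator, ...) to the exposure's
#' effect-allele orientation.  For non-palindromic SNPs the allele pair is
#' matched directly or after a strand (complement) flip, flipping the sign of
#' beta and replacing eaf by 1 - eaf where the stated effect allele is the
#' exposure's other allele.  Palindromic (A/T, C/G) SNPs are strand-resolved
#' by comparing effect-allele frequencies to 0.5 on both sides; when either
#' frequency lies inside `[palindrome_maf_limit, 1 - palindrome_maf_limit]`
#' (or is missing) the SNP is dropped as an ambiguous palindrome.  SNPs
#' absent from any study, or with irreconcilable allele pairs, are dropped
#' with reasons `"missing"` and `"allele mismatch"`.
#'
#' Every exposure SNP appears exactly once in the retained set or the
#' `dropped` attribute, and harmonizing an already-harmonized set is a
#' no-op.
#'
#' @param exposure a `sumstats` table of the exposure's instruments.
#' @param others a single `sumstats` table (treated as the outcome) or a
#'   named list of tables; names become column suffixes.
#' @param palindrome_maf_limit frequencies within this distance of 0.5 on
#'   either side make a palindromic SNP ambiguous (default 0.42, the common
#'   MR-tooling window).
#' @return A data.frame of class `harmonized_set` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `pval_exposure` and, per aligned study `s`, `beta_s`,
#'   `se_s`, `eaf_s`, `pval_s`.  Attribute `dropped` lists `(snp_id, reason)`.
#' @export
harmonize <- function(exposure, others, palindrome_maf_limit = 0.42) {
  if (nrow(exposure) == 0L) stop("exposure records are empty")
  if (is.data.frame(others)) others <- list(outcome = others)
  if (is.null(names(others)) || any(names(others) == "")) {
    stop("'others' must be a named list of sumstats tables")
  }
  exposure <- as.data.frame(exposure)
  if (anyDuplicated(exposure$snp_id)) stop("duplicated snp_id in exposure")
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids) > 0L) {
      dropped <<- rbind(dropped, data.frame(snp_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }

  present <- rep(TRUE, nrow(exposure))
  for (s in others) present <- present & exposure$snp_id %in% s$snp_id
  drop(exposure$snp_id[!present], "missing")
  keep <- exposure[present, , drop = FALSE]

  out <- data.frame(
    snp_id = keep$snp_id,
    effect_allele = keep$effect_allele,
    other_allele = keep$other_allele,
    beta_exposure = keep$beta,
    se_exposure = keep$se,
    eaf_exposure = keep$eaf,
    pval_exposure = keep$pval,
    stringsAsFactors = FALSE
  )
  retained <- rep(TRUE, nrow(keep))
  reasons <- character(nrow(keep))
  for (nm in names(others)) {
    s <- as.data.frame(others[[nm]])
    idx <- match(keep$snp_id, s$snp_id)
    srec <- s[idx, , drop = FALSE]
    action <- align_alleles(keep$effect_allele, keep$other_allele, keep$eaf,
                            srec$effect_allele, srec$other_allele, srec$eaf,
                            srec$beta, palindrome_maf_limit)
    beta_s <- ifelse(action == "flip", -srec$beta, srec$beta)
    eaf_s <- ifelse(action == "flip", 1 - srec$eaf, srec$eaf)
    bad <- !(action %in% c("keep", "flip"))
    reasons[bad & retained] <- action[bad & retained]
    retained <- retained & !bad
    out[[paste0("beta_", nm)]] <- beta_s
    out[[paste0("se_", nm)]] <- srec$se
    out[[paste0("eaf_", nm)]] <- eaf_s
    out[[paste0("pval_", nm)]] <- srec$pval
  }
  drop(out$snp_id[!retained], reasons[!retained])
  out <- out[retained, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = dropped, studies = names(others),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  d <- attr(x, "dropped")
  cat(sprintf("Harmonized set: %d SNP(s) aligned to studies [%s]; %d dropped\n",
              nrow(x), paste(attr(x, "studies"), collapse = ", "),
              if (is.null(d)) 0L else nrow(d)))
  print(as.data.frame(x), ...)
  invisible(x)
}
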