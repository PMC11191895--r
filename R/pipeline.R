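#' Pipeline configuration
#'
#' Method and threshold settings for the two-phase workflow: per-trait-class
#' instrument selection, effects-model rule, bootstrap and simulation sizes,
#' the nominal screening level, and a mandatory seed.
#'
#' @param exposure_pval instrument p-value threshold for exposures
#'   (default 1e-5, the conventional relaxed microbiome threshold).
#' @param mediator_pval instrument p-value threshold for mediators
#'   (default 5e-6, typical for protein quantitative trait loci).
#' @param clump_window_kb,clump_r2,f_min shared clumping / strength
#'   settings (see [instrument_config()]).
#' @param alpha nominal significance level used throughout screening.
#' @param effects_model IVW and meta-analysis model rule
#'   (`"auto"`/`"fixed"`/`"random"`).
#' @param n_boot weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulations.
#' @param palindrome_maf_limit harmonization ambiguity window.
#' @param seed integer seed driving every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure_pval = 1e-5, mediator_pval = 5e-6,
                            clump_window_kb = 10000, clump_r2 = 0.001,
                            f_min = 10, alpha = 0.05,
                            effects_model = "auto", n_boot = 1000,
                            n_sim = 1000, palindrome_maf_limit = 0.42,
                            seed) {
  if (missing(seed)) stop("a pipeline seed is required")
  structure(list(
    exposure_config = instrument_config(exposure_pval, clump_window_kb,
                                        clump_r2, f_min),
    mediator_config = instrument_config(mediator_pval, clump_window_kb,
                                        clump_r2, f_min),
    alpha = alpha, effects_model = effects_model, n_boot = n_boot,
    n_sim = n_sim, palindrome_maf_limit = palindrome_maf_limit,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

analyze_pair <- function(trait_name, trait_data, outcome_name, datasets,
                         ld, iv_cfg, cfg) {
  iv <- select_instruments(trait_data, ld, iv_cfg)
  if (nrow(iv) < 4L) {
    stop("fewer than 4 instruments selected for ", trait_name)
  }
  per_dataset <- list()
  ivw_list <- list()
  for (ds in names(datasets)) {
    h <- harmonize(iv, list(outcome = datasets[[ds]]),
                   cfg$palindrome_maf_limit)
    methods <- mr_all_methods(h, n_boot = cfg$n_boot,
                              seed = sub_seed(cfg$seed, paste(trait_name,
                                                              outcome_name,
                                                              ds, "wm")),
                              effects_model = cfg$effects_model)
    presso <- if (nrow(h) >= 4L) {
      mr_presso(h, n_sim = cfg$n_sim,
                seed = sub_seed(cfg$seed, paste(trait_name, outcome_name,
                                                ds, "presso")))
    } else NULL
    per_dataset[[ds]] <- list(harmonized = h, methods = methods,
                              presso = presso)
    ivw_list[[ds]] <- methods[methods$method == "ivw", ]
  }
  meta <- meta_analyze(do.call(rbind, ivw_list), model = cfg$effects_model)
  disc <- per_dataset[[1]]
  ivw_row <- disc$methods[disc$methods$method == "ivw", ]
  # screening uses the outlier-corrected IVW when MR-PRESSO flagged any
  ivw_beta <- ivw_row$beta
  ivw_pval <- ivw_row$pval
  if (!is.null(disc$presso) && length(disc$presso$outliers) > 0L) {
    corr <- disc$presso$beta_outlier_corrected
    ivw_beta <- corr$beta
    ivw_pval <- corr$pval
  }
  list(
    instruments = iv,
    datasets = per_dataset,
    meta = meta,
    screen_row = data.frame(
      exposure = trait_name, outcome = outcome_name,
      n_snps = ivw_row$n_snps,
      ivw_beta = ivw_beta, ivw_pval = ivw_pval,
      egger_beta = disc$methods$beta[disc$methods$method == "egger"],
      wm_beta = disc$methods$beta[disc$methods$method == "weighted_median"],
      presso_global_pval = if (is.null(disc$presso)) NA_real_ else
        disc$presso$global_pval,
      meta_pval = meta$pval_pooled,
      stringsAsFactors = FALSE
    )
  )
}

#' Phase 1: screen exposures and mediators against the outcomes
#'
#' For every exposure-outcome and mediator-outcome pair: select
#' instruments, harmonize against each outcome dataset (discovery plus
#' replication), run IVW / MR-Egger / weighted median with Cochran's Q,
#' MR-PRESSO, and the replication meta-analysis, then screen candidates by
#' the conjunction rule of [screen_candidates()].  A failure in one pair is
#' logged and never aborts the batch.
#'
#' @param exposures named list of full exposure `sumstats` tables.
#' @param mediators named list of full mediator `sumstats` tables.
#' @param outcome_datasets named list of at least two outcome `sumstats`
#'   tables for the same outcome trait (first = discovery, rest =
#'   replication).
#' @param ld an [ld_reference()].
#' @param cfg a [pipeline_config()].
#' @param outcome_name label for the outcome trait in reports.
#' @return A list of class `phase1_result`: `exposure_screen` and
#'   `mediator_screen` (screening tables with `candidate`/`reason`),
#'   `details` (per-pair full results), `failures` (pair, stage, message).
#' @export
run_phase1 <- function(exposures, mediators, outcome_datasets, ld, cfg,
                       outcome_name = "outcome") {
  stopifnot(inherits(cfg, "pipeline_config"),
            length(outcome_datasets) >= 2L)
  details <- list()
  failures <- data.frame(pair = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  screen_class <- function(traits, iv_cfg, class_label) {
    rows <- list()
    for (nm in names(traits)) {
      res <- tryCatch(
        analyze_pair(nm, traits[[nm]], outcome_name, outcome_datasets, ld,
                     iv_cfg, cfg),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <<- rbind(failures, data.frame(
          pair = paste(nm, outcome_name, sep = " -> "),
          message = conditionMessage(res), stringsAsFactors = FALSE))
      } else {
        details[[paste(class_label, nm, sep = ":")]] <<- res
        rows[[nm]] <- res$screen_row
      }
    }
    if (length(rows) == 0L) return(NULL)
    screen_candidates(do.call(rbind, rows), alpha = cfg$alpha)
  }
  exposure_screen <- screen_class(exposures, cfg$exposure_config, "exposure")
  mediator_screen <- screen_class(mediators, cfg$mediator_config, "mediator")
  structure(list(exposure_screen = exposure_screen,
                 mediator_screen = mediator_screen,
                 details = details, failures = failures,
                 outcome_name = outcome_name),
            class = "phase1_result")
}

#' Phase 2: multivariable MR and mediation decomposition
#'
#' For each candidate exposure-mediator-outcome triple whose
#' exposure-to-mediator link is significant (univariable IVW p below the
#' configured level): estimate `beta1` (exposure to mediator), build the
#' joint instrument set, run multivariable MR for `beta4` (mediator,
#' adjusted) and `beta5` (exposure, adjusted), and decompose the mediation.
#' Univariable `beta2`/`beta3` are attached for context.  Triples that fail
#' (collinearity, too few joint instruments) are skipped with a recorded
#' reason.
#'
#' @param phase1 a `phase1_result`.
#' @param exposures,mediators the same named lists given to [run_phase1()].
#' @param outcome_data the discovery outcome `sumstats` table.
#' @param ld an [ld_reference()].
#' @param cfg the [pipeline_config()].
#' @return A list of class `phase2_result` with `mediation` (one row per
#'   triple: `exposure`, `mediator`, `outcome`, `beta1`..`beta5`,
#'   `indirect`, `total`, `proportion`, `proportion_label`, `established`)
#'   and `skipped` (triple, reason).
#' @export
run_phase2 <- function(phase1, exposures, mediators, outcome_data, ld, cfg) {
  stopifnot(inherits(phase1, "phase1_result"))
  es <- phase1$exposure_screen
  ms <- phase1$mediator_screen
  rows <- list()
  skipped <- data.frame(triple = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(label, why) {
    skipped <<- rbind(skipped, data.frame(triple = label, reason = why,
                                          stringsAsFactors = FALSE))
  }
  cand_exp <- if (is.null(es)) character(0) else es$exposure[es$candidate]
  cand_med <- if (is.null(ms)) character(0) else ms$exposure[ms$candidate]
  if (length(cand_exp) == 0L || length(cand_med) == 0L) {
    message("phase 2 skipped: empty candidate set after screening")
    return(structure(list(mediation = NULL, skipped = skipped),
                     class = "phase2_result"))
  }
  for (e in cand_exp) {
    for (m in cand_med) {
      label <- paste(e, m, phase1$outcome_name, sep = " -> ")
      res <- tryCatch({
        exp_iv <- phase1$details[[paste0("exposure:", e)]]$instruments
        med_iv <- phase1$details[[paste0("mediator:", m)]]$instruments
        h1 <- harmonize(exp_iv, list(mediator = mediators[[m]]),
                        cfg$palindrome_maf_limit)
        if (nrow(h1) < 2L) stop("too few instruments shared with mediator")
        b1 <- mr_ivw(h1, cfg$effects_model)
        if (b1$pval >= cfg$alpha) {
          skip(label, "exposure-mediator link not significant")
          NULL
        } else {
          joint <- build_joint_instruments(exp_iv, med_iv, exposures[[e]],
                                           mediators[[m]], outcome_data, ld,
                                           cfg$exposure_config,
                                           cfg$palindrome_maf_limit)
          mv <- mvmr_ivw(joint, exposures = c("exposure", "mediator"))
          e_det <- phase1$details[[paste0("exposure:", e)]]
          m_det <- phase1$details[[paste0("mediator:", m)]]
          b3 <- e_det$screen_row$ivw_beta
          b2 <- m_det$screen_row$ivw_beta
          dec <- decompose_mediation(
            beta1 = b1$beta, beta4 = mv$betas[["mediator"]],
            beta5 = mv$betas[["exposure"]],
            se1 = b1$se, se4 = mv$ses[["mediator"]],
            se5 = mv$ses[["exposure"]],
            p1 = b1$pval, p4 = mv$pvals[["mediator"]],
            p5 = mv$pvals[["exposure"]],
            beta2 = b2, beta3 = b3, alpha = cfg$alpha)
          data.frame(exposure = e, mediator = m,
                     outcome = phase1$outcome_name,
                     beta1 = dec$beta1, beta2 = dec$beta2, beta3 = dec$beta3,
                     beta4 = dec$beta4, beta5 = dec$beta5,
                     indirect = dec$indirect, total = dec$total,
                     proportion = dec$proportion,
                     proportion_label = if (dec$established)
                       dec$proportion_label else "not established",
                     established = dec$established,
                     n_joint_snps = mv$n_snps,
                     stringsAsFactors = FALSE)
        }
      }, error = function(err) {
        skip(label, conditionMessage(err))
        NULL
      })
      if (!is.null(res)) rows[[label]] <- res
    }
  }
  mediation <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  if (!is.null(mediation)) rownames(mediation) <- NULL
  structure(list(mediation = mediation, skipped = skipped),
            class = "phase2_result")
}

#' Run the full two-phase mediation workflow
#'
#' Convenience wrapper: [run_phase1()] then [run_phase2()], returning both
#' plus a manifest of the settings used so every reported number is
#' reproducible from the inputs and the seed alone.
#'
#' @inheritParams run_phase1
#' @return list with `phase1`, `phase2` and `manifest`.
#' @export
run_pipeline <- function(exposures, mediators, outcome_datasets, ld, cfg,
                         outcome_name = "outcome") {
  p1 <- run_phase1(exposures, mediators, outcome_datasets, ld, cfg,
                   outcome_name)
  p2 <- run_phase2(p1, exposures, mediators, outcome_datasets[[1]], ld, cfg)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mrmediate")),
    seed = cfg$seed, alpha = cfg$alpha,
    effects_model = cfg$effects_model, n_boot = cfg$n_boot,
    n_sim = cfg$n_sim,
    exposure_pval = cfg$exposure_config$pval_threshold,
    mediator_pval = cfg$mediator_config$pval_threshold,
    clump_window_kb = cfg$exposure_config$clump_window_kb,
    clump_r2 = cfg$exposure_config$clump_r2,
    f_min = cfg$exposure_config$f_min,
    n_exposures = length(exposures), n_mediators = length(mediators),
    n_outcome_datasets = length(outcome_datasets),
    presso_order = "per dataset, before meta-analysis"
  )
  list(phase1 = p1, phase2 = p2, manifest = manifest)
}
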