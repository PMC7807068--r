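#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings: the input mode (simulate a cohort or read
#' the three delimited files), QC thresholds, optional obesity strata, the
#' forest and selection configurations, GMDR settings, and the risk-profile
#' codings. A master seed deterministically derives every stage seed, so a
#' config reruns to identical numbers.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param sim A [sim_spec()] (simulate mode).
#' @param files Named list with `genotype`, `covariate`, `outcome` paths
#'   (files mode).
#' @param qc List with `max_missing_rate`, `min_hwe_p`.
#' @param strata Named list of [stratum_spec()]s to analyse (empty = overall
#'   only).
#' @param forest A [forest_config()].
#' @param selection A [selection_config()].
#' @param gmdr List with `folds`, `max_order`, `n_perm`, `max_pool`.
#' @param profile List with `lifestyle_risk` (tibble understood by
#'   [assign_risk_lifestyle()]), `stratifier` (exposure column for the
#'   joint-effect table) and `stratifier_cutoff`.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            sim = sim_spec(), files = NULL,
                            qc = list(max_missing_rate = 0.02,
                                      min_hwe_p = 1e-4),
                            strata = list(),
                            forest = forest_config(),
                            selection = selection_config(),
                            gmdr = list(folds = 10, max_order = 3,
                                        n_perm = 199, max_pool = 25),
                            profile = list(
                              lifestyle_risk = default_lifestyle_risk(),
                              stratifier = "alcohol_g_day",
                              stratifier_cutoff = 18),
                            seed = 1) {
  mode <- match.arg(mode)
  if (mode == "files" &&
      !all(c("genotype", "covariate", "outcome") %in% names(files)))
    abort("files mode needs genotype, covariate and outcome paths",
          class = "riskforest_config_error")
  structure(
    list(mode = mode, sim = sim, files = files, qc = qc, strata = strata,
         forest = forest, selection = selection, gmdr = gmdr,
         profile = profile, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full risk-profiling pipeline
#'
#' Simulate or read the cohort, apply genotype QC, run the two-stage
#' multimodal forest selection, the GMDR gene-gene interaction search on the
#' selected SNPs, and the combined genotype-lifestyle dose-response Cox
#' profiling — overall and in any configured strata. All stage outputs are
#' written as tab-delimited reports plus a JSON manifest recording inputs,
#' resolved settings and seeds; rerunning the same config reproduces every
#' number exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the cohort, per-analysis results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  coh <- if (config$mode == "simulate") {
    simulate_cohort(config$sim, derive_seed(config$seed, "simulate"))
  } else {
    read_cohort(config$files$genotype, config$files$covariate,
                config$files$outcome, config$files$schema)
  }
  coh <- qc_filter(coh, config$qc$max_missing_rate, config$qc$min_hwe_p)
  readr::write_tsv(qc_report(coh), file.path(out_dir, "qc_report.tsv"))

  analyses <- c(list(overall = coh), unlist(lapply(
    names(config$strata), function(nm) {
      st <- stratify(coh, config$strata[[nm]])
      setNames(st, paste0(nm, "_", names(st)))
    }), recursive = FALSE))

  results <- list()
  for (nm in names(analyses)) {
    results[[nm]] <- tryCatch(
      run_one_analysis(analyses[[nm]], config, nm, out_dir),
      error = function(e) {
        warn(paste0("analysis '", nm, "' failed: ", conditionMessage(e)))
        list(error = conditionMessage(e))
      }
    )
  }

  manifest <- list(
    mode = config$mode,
    n_subjects = n_subjects(coh),
    n_events = sum(coh$data$event),
    n_snps_post_qc = ncol(coh$genotypes),
    seed = config$seed,
    forest = config$forest[c("n_trees", "nsplit", "min_node_events",
                             "max_depth", "vimp_reps")],
    selection = config$selection[c("delta", "vimp_threshold")],
    gmdr = config$gmdr,
    analyses = lapply(results, function(r) {
      if (!is.null(r$error)) list(error = r$error)
      else list(selected = r$selected, best_gmdr = r$best_gmdr$model %||% NA)
    }),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = coh, results = results, manifest = manifest))
}

run_one_analysis <- function(coh, config, label, out_dir) {
  snps <- colnames(coh$genotypes)
  lifestyles <- setdiff(names(coh$data),
                        c("subject_id", "time_years", "event"))
  frame <- as_analysis_frame(coh)
  fc <- config$forest
  fc$seed <- derive_seed(config$seed, paste0("select_", label))
  sel <- select_variables(frame, snps, lifestyles, fc, config$selection)
  readr::write_tsv(sel$stage2$ranking,
                   file.path(out_dir, paste0(label, "_ranking.tsv")))
  readr::write_tsv(tibble::as_tibble(sel$stage2$curve),
                   file.path(out_dir, paste0(label, "_nested_curve.tsv")))

  final <- sel$stage2$selected
  sel_snps <- intersect(final, snps)
  pool <- if (length(sel_snps) >= 2) sel_snps else
    head(intersect(sel$stage2$ranking$variable, snps), 3)
  gm <- NULL; best <- NULL
  if (length(pool) >= 2) {
    scores <- gmdr_scores(frame,
                          covariates = intersect(final, lifestyles))
    gm <- gmdr_search(scores, frame[pool], pool,
                      max_order = min(config$gmdr$max_order, length(pool)),
                      folds = config$gmdr$folds,
                      seed = derive_seed(config$seed, paste0("gmdr_", label)),
                      strata = frame$event, n_perm = config$gmdr$n_perm,
                      max_pool = config$gmdr$max_pool)
    best <- gmdr_select_best(gm, folds = config$gmdr$folds)
    readr::write_tsv(tidy(gm),
                     file.path(out_dir, paste0(label, "_gmdr.tsv")))
  }

  profile <- NULL
  prof_cfg <- config$profile
  risk_snps <- if (length(sel_snps)) sel_snps else pool
  if (length(risk_snps)) {
    coding <- derive_risk_coding(frame, risk_snps)
    gtab <- assign_risk_genotype(frame, coding)
    life_risk <- prof_cfg$lifestyle_risk[
      prof_cfg$lifestyle_risk$variable %in% names(frame), ]
    btab <- assign_risk_lifestyle(frame, life_risk)
    frame$risk_score <- combine_gene_lifestyle(gtab$G, btab$B)
    frame$exposure_high <-
      as.integer(frame[[prof_cfg$stratifier]] >= prof_cfg$stratifier_cutoff)
    covars <- setdiff(intersect(final, lifestyles),
                      c(prof_cfg$stratifier, life_risk$variable))
    profile <- joint_effect_table(frame, "risk_score", "exposure_high",
                                  covariates = covars)
    readr::write_tsv(tibble::as_tibble(profile),
                     file.path(out_dir, paste0(label, "_risk_profile.tsv")))
  }

  list(selected = final, stage1 = sel[c("stage1_snps", "stage1_lifestyles")],
       stage2 = sel$stage2, gmdr = gm, best_gmdr = best, profile = profile)
}
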