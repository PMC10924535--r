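# End-to-end orchestration: simulate (or ingest) -> grade -> map -> infer
# -> parcels, with seed-reproducible artifacts and a recovery report
# against synthetic ground truth.

#' Run the full lesion-symptom mapping pipeline
#'
#' Executes every stage for each neurocognitive domain and writes all
#' artifacts under `out_dir`: the brain mask and atlas, per-domain grouping
#' CSVs, observed statistic maps, permutation-null dumps (JSON), p/q maps,
#' significance masks at every alpha, per-parcel coverage tables, heatmap
#' matrices, and a provenance JSON (seed, config hash, stage counts). A
#' rerun with the same config and seed reproduces every file byte for
#' byte.
#'
#' @param config A [sim_config()] describing the synthetic cohort (used for
#'   any of `cohort`, `scores`, `atlas` not supplied).
#' @param out_dir Output directory (created; must be empty or absent).
#' @param cohort,scores,atlas,truth Optional pre-built inputs; by default
#'   they are simulated from `config`.
#' @param domains Domains to analyze (default: all in the score table).
#' @param statistic,inference,n_permutations,alpha_levels,rr_threshold
#'   Passed to [vlsm()].
#' @return Invisibly, a list with the per-domain `vlsm` fits, coverage
#'   tables, the recovery report (if ground truth is available) and the
#'   artifact `paths`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         cohort = NULL, scores = NULL, atlas = NULL,
                         truth = NULL, domains = NULL,
                         statistic = "t", inference = "perm95",
                         n_permutations = 1000,
                         alpha_levels = c(0.05, 0.2), rr_threshold = 0.03) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)))
    .stop_validation("`out_dir` exists and is not empty: %s", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) {
      sim <- simulate_cohort(config)
      cohort <- sim$cohort
      truth <- truth %||% sim$truth
    }
    if (is.null(scores)) {
      if (is.null(truth))
        .stop_validation("scores can only be simulated with ground truth")
      scores <- simulate_scores(cohort, truth, config)
    }
    if (is.null(atlas))
      atlas <- make_atlas(cohort$space, config$n_parcels,
                          seed = .derive_seed(config$seed, "atlas"))
    .check_grid(atlas$labels, cohort$space, "atlas")
    save_volume(cohort$space$brain_mask + 0, cohort$space,
                file.path(out_dir, "brain_mask.nii.gz"))
    save_atlas(atlas, file.path(out_dir, "atlas.nii.gz"),
               file.path(out_dir, "atlas_parcels.csv"))
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

    stage <- "classify"
    assessments <- assess_scores(scores, subjects = cohort$subject_ids)
    write_assessments(assessments, file.path(out_dir, "assessments.csv"))
    if (is.null(domains)) domains <- unique(assessments$domain)

    fits <- list(); coverages <- list(); skipped <- character(0)
    for (dom in domains) {
      stage <- sprintf("map/infer [%s]", dom)
      groups <- build_groups(assessments, dom, subjects = cohort$subject_ids)
      if (length(groups$affected) < 2L || length(groups$control) < 2L) {
        warning(sprintf(
          "domain `%s`: group sizes %d vs %d too small, skipped", dom,
          length(groups$affected), length(groups$control)), call. = FALSE)
        skipped <- c(skipped, dom)
        next
      }
      gdf <- data.frame(
        subject_id = c(groups$affected, groups$control),
        group = rep(c("affected", "control"),
                    c(length(groups$affected), length(groups$control))))
      write.csv(gdf, file.path(out_dir, sprintf("%s_groups.csv", dom)),
                row.names = FALSE)
      fit <- vlsm(cohort, groups, statistic = statistic,
                  inference = inference, n_permutations = n_permutations,
                  alpha = alpha_levels, rr_threshold = rr_threshold,
                  seed = config$seed)
      fits[[dom]] <- fit
      save_map(fit$observed,
               file.path(out_dir, sprintf("%s_%s_map.nii.gz", dom,
                                          statistic)))
      save_map(fit$p, file.path(out_dir, sprintf("%s_p_%s.nii.gz", dom,
                                                 inference)))
      if (!is.null(fit$q))
        save_map(fit$q, file.path(out_dir, sprintf("%s_q.nii.gz", dom)))
      if (!is.null(fit$null))
        .write_json(list(mode = fit$null$mode,
                         percentile_q = fit$null$percentile_q,
                         n_permutations = fit$null$n_permutations,
                         exhaustive = fit$null$exhaustive,
                         seed = fit$null$seed,
                         summary_values = fit$null$summary_values),
                    file.path(out_dir, sprintf("%s_null.json", dom)))
      stage <- sprintf("parcels [%s]", dom)
      for (a in alpha_levels) {
        mk <- fit$masks[[sprintf("alpha_%g", a)]]
        save_map(mk, file.path(out_dir, sprintf("%s_sig_a%g.nii.gz", dom, a)))
        cov <- parcel_coverage(mk, atlas, domain = dom, alpha = a)
        write.csv(cov, file.path(out_dir,
                                 sprintf("%s_coverage_a%g.csv", dom, a)),
                  row.names = FALSE)
        coverages[[sprintf("%s_a%g", dom, a)]] <- cov
      }
    }

    stage <- "heatmaps"
    run_domains <- setdiff(domains, skipped)
    for (a in alpha_levels) {
      tabs <- coverages[sprintf("%s_a%g", run_domains, a)]
      names(tabs) <- run_domains
      if (length(tabs) == 0L) next
      for (cl in c("cortical", "subcortical")) {
        hm <- heatmap_matrix(tabs, class_filter = cl)
        write.csv(data.frame(parcel = rownames(hm), hm,
                             check.names = FALSE),
                  file.path(out_dir, sprintf("heatmap_%s_a%g.csv", cl, a)),
                  row.names = FALSE)
      }
    }

    stage <- "report"
    recovery <- NULL
    if (!is.null(truth)) {
      recovery <- lapply(fits, function(fit) {
        lapply(fit$masks, function(mk)
          evaluate_recovery(mk, truth, cohort$space))
      })
      .write_json(recovery, file.path(out_dir, "recovery.json"))
    }
    counts <- list(
      n_subjects = .n_subjects(cohort),
      n_brain_voxels = sum(cohort$space$brain_mask),
      domains_run = as.list(run_domains),
      domains_skipped = as.list(skipped),
      n_significant = lapply(fits, function(f)
        lapply(f$masks, function(m) sum(m$mask)))
    )
    .write_json(list(seed = config$seed,
                     config_hash = .md5_of(unclass(config)),
                     config = unclass(config),
                     statistic = statistic, inference = inference,
                     n_permutations = n_permutations,
                     alpha_levels = alpha_levels, counts = counts),
                file.path(out_dir, "provenance.json"))
    list(fits = fits, coverages = coverages, recovery = recovery,
         assessments = assessments, truth = truth, atlas = atlas,
         cohort = cohort,
         paths = sort(dir(out_dir, full.names = TRUE)))
  }, error = function(e) {
    .write_json(list(failed_stage = stage, error = conditionMessage(e)),
                file.path(out_dir, "provenance_partial.json"))
    stop(sprintf("pipeline failed at stage [%s]: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Sensitivity and specificity of a significance mask
#'
#' Voxelwise recovery of the planted effect region:
#' sensitivity = |sig ∩ effect| / |effect| and
#' specificity = |¬sig ∩ ¬effect ∩ brain| / |¬effect ∩ brain|.
#'
#' @param sig A `sig_mask` or logical 3D array.
#' @param truth A `ground_truth` (or logical effect-region array).
#' @param space The [template_space()].
#' @return List with `sensitivity`, `specificity`, `n_significant`,
#'   `n_effect`.
#' @export
evaluate_recovery <- function(sig, truth, space) {
  .check_space(space)
  if (inherits(sig, "sig_mask")) sig <- sig$mask
  effect <- if (inherits(truth, "ground_truth")) truth$effect_mask else truth
  .check_grid(sig, space, "significance mask")
  .check_grid(effect, space, "effect region")
  if (!any(effect)) .stop_validation("empty effect region")
  brain <- space$brain_mask
  neg <- brain & !effect
  list(sensitivity = sum(sig & effect) / sum(effect),
       specificity = sum(!sig & neg) / sum(neg),
       n_significant = sum(sig & brain),
       n_effect = sum(effect))
}
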