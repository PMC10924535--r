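# Simulation studies: operating characteristics of the inference modes on
# synthetic cohorts (type-I error calibration under the global null,
# per-voxel p-value validity, and recovery of a planted effect). These are
# the package's own validation experiments and the basis of its
# reproducibility report.

#' Family-wise error study under the global null
#'
#' Repeatedly simulates cohorts with `effect_strength = 0` (lesion
#' placement independent of group labels, so labels are exchangeable),
#' groups subjects by the generator's ground-truth labels, and records for
#' each replicate whether any voxel is significant at `alpha` under the
#' minimum-statistic null and under the Perm95 null (shared permutation
#' stream), plus the per-voxel uncorrected t-permutation rejection rate.
#'
#' @param n_sims Number of simulated datasets.
#' @param config Base [sim_config()]; its `effect_strength` is forced to 0.
#' @param n_permutations Permutations per dataset (default 199).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; replicate i uses `seed + i`.
#' @return List: `fwe_min_stat`, `fwe_perm95`, `fwe_pervoxel` (fraction of
#'   replicates with any significant voxel), `pervoxel_rate` (mean
#'   per-voxel rejection rate), `n_sims`, and the per-replicate `detail`
#'   data.frame.
#' @export
fwe_study <- function(n_sims, config = sim_config(grid_shape = c(16, 16, 16),
                                                  n_subjects = 40,
                                                  n_affected = 15),
                      n_permutations = 199, alpha = 0.05, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  detail <- data.frame(any_min = logical(n_sims),
                       any_p95 = logical(n_sims),
                       any_pervoxel = logical(n_sims),
                       pervoxel_rate = numeric(n_sims))
  for (i in seq_len(n_sims)) {
    cfg <- config
    cfg$effect_strength <- 0
    cfg$seed <- as.integer(seed + i)
    sim <- simulate_cohort(cfg)
    ids <- sim$cohort$subject_ids
    groups <- vlsm_groups(affected = ids[sim$truth$affected],
                          control = ids[!sim$truth$affected])
    pc_min <- perm_config(n_permutations = n_permutations,
                          mode = "min_stat", seed = cfg$seed,
                          exhaustive_limit = 0)
    pc_p95 <- perm_config(n_permutations = n_permutations,
                          mode = "perm_percentile", seed = cfg$seed,
                          exhaustive_limit = 0)
    inp_n <- .n_subjects(sim$cohort)
    perms <- permute_labels(inp_n, length(groups$affected), n_permutations,
                            seed = .derive_seed(cfg$seed, "perm"),
                            exhaustive_limit = 0)
    obs <- t_map(sim$cohort, groups)
    null_min <- build_null(sim$cohort, groups, pc_min, perms = perms)
    null_p95 <- build_null(sim$cohort, groups, pc_p95, perms = perms)
    p_min <- p_map_fwe(obs, null_min)
    p_p95 <- p_map_fwe(obs, null_p95)
    pv <- p_map_pervoxel(sim$cohort, groups,
                         perm_config(n_permutations = n_permutations,
                                     mode = "per_voxel", seed = cfg$seed,
                                     exhaustive_limit = 0),
                         statistic = "t")
    detail$any_min[i] <- any(p_min$values[p_min$valid] < alpha)
    detail$any_p95[i] <- any(p_p95$values[p_p95$valid] < alpha)
    pvv <- pv$values[pv$valid]
    detail$any_pervoxel[i] <- any(pvv < alpha)
    detail$pervoxel_rate[i] <- mean(pvv < alpha)
  }
  list(fwe_min_stat = mean(detail$any_min),
       fwe_perm95 = mean(detail$any_p95),
       fwe_pervoxel = mean(detail$any_pervoxel),
       pervoxel_rate = mean(detail$pervoxel_rate),
       n_sims = n_sims, alpha = alpha, detail = detail)
}

#' Per-voxel RR p-value distribution under the global null
#'
#' Repeatedly simulates global-null cohorts and records the per-voxel
#' relative-risk permutation p-value at one fixed voxel (default: the
#' centre of the configured effect region, where lesions are frequent
#' enough for the statistic to be defined). Valid permutation p-values are
#' super-uniform under the null: their empirical CDF should not exceed the
#' uniform CDF beyond sampling error.
#'
#' @param n_sims Number of simulated datasets.
#' @param config Base [sim_config()] (effect disabled internally).
#' @param n_permutations Permutations per dataset.
#' @param voxel Integer triple; default `config$effect_center`.
#' @param rr_threshold Mask binarization threshold (default 0.03).
#' @param seed Master seed.
#' @return List: `p` (vector of p-values, NA where the voxel's RR was
#'   undefined in a replicate), `ks_dplus` (one-sided KS statistic of the
#'   non-NA p-values against Uniform(0,1)), `n_used`.
#' @export
rr_uniformity_study <- function(n_sims,
                                config = sim_config(
                                  grid_shape = c(16, 16, 16),
                                  n_subjects = 40, n_affected = 15),
                                n_permutations = 199, voxel = NULL,
                                rr_threshold = 0.03, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(voxel)) voxel <- round(config$effect_center)
  p <- rep(NA_real_, n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- config
    cfg$effect_strength <- 0
    cfg$seed <- as.integer(seed + i)
    sim <- simulate_cohort(cfg)
    ids <- sim$cohort$subject_ids
    groups <- vlsm_groups(affected = ids[sim$truth$affected],
                          control = ids[!sim$truth$affected])
    pv <- p_map_pervoxel(sim$cohort, groups,
                         perm_config(n_permutations = n_permutations,
                                     mode = "per_voxel", seed = cfg$seed,
                                     exhaustive_limit = 0),
                         statistic = "rr", rr_threshold = rr_threshold)
    if (pv$valid[voxel[1], voxel[2], voxel[3]])
      p[i] <- pv$values[voxel[1], voxel[2], voxel[3]]
  }
  used <- p[!is.na(p)]
  n <- length(used)
  dplus <- if (n > 0) max(seq_len(n) / n - sort(used)) else NA_real_
  list(p = p, ks_dplus = dplus, n_used = n)
}

#' Recovery of a planted effect region
#'
#' Runs the full analysis on one synthetic cohort with a planted effect:
#' scores are simulated from lesion overlap with the effect region, graded
#' into severity bands, the severe-only affected group is formed, the
#' Perm95 map fitted, and the significance mask compared with the
#' ground-truth region. Also reports the parcel ranking: which atlas
#' parcel tops the coverage table and whether it is the parcel containing
#' the effect-region centre.
#'
#' @param config A [sim_config()] with a planted effect
#'   (`effect_strength > 0`).
#' @param domain Domain used for grouping (default attention/executive).
#' @param n_permutations Permutations (default 1000).
#' @param alpha Mask level assessed for recovery (default 0.2, the
#'   clinically significant threshold).
#' @param inference Inference mode (default `"perm95"`).
#' @param calibrate If `TRUE` (default), replace the config's
#'   `deficit_shift` with [calibrate_deficit_shift()] at
#'   `calibrate_target`, so the stated fraction of affected subjects is
#'   expected to be recruited into the severe group.
#' @param calibrate_target Target recruited fraction (default 0.6).
#' @return List: `sensitivity`, `specificity`, `n_significant`,
#'   `top_parcel_label`, `effect_parcel_label`, `top_is_effect_parcel`,
#'   `frac_affected_severe` (fraction of ground-truth affected subjects
#'   graded severe), `fit`, `coverage`.
#' @export
recovery_study <- function(config = sim_config(grid_shape = c(24, 24, 24)),
                           domain = "attention_executive",
                           n_permutations = 1000, alpha = 0.2,
                           inference = "perm95", calibrate = TRUE,
                           calibrate_target = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  if (calibrate)
    config$deficit_shift <- calibrate_deficit_shift(config, calibrate_target)
  sim <- simulate_cohort(config)
  scores <- simulate_scores(sim$cohort, sim$truth, config)
  assessments <- assess_scores(scores, subjects = sim$cohort$subject_ids)
  groups <- build_groups(assessments, domain,
                         subjects = sim$cohort$subject_ids)
  sev <- assessments$subject_id[assessments$domain == domain &
                                  assessments$group == "affected"]
  truth_ids <- names(sim$truth$affected)[sim$truth$affected]
  fit <- vlsm(sim$cohort, groups, statistic = "t", inference = inference,
              n_permutations = n_permutations,
              alpha = unique(c(0.05, alpha)), seed = config$seed)
  mask <- fit$masks[[sprintf("alpha_%g", alpha)]]
  rec <- evaluate_recovery(mask, sim$truth, sim$cohort$space)
  atlas <- make_atlas(sim$cohort$space, config$n_parcels,
                      seed = .derive_seed(config$seed, "atlas"))
  cov <- parcel_coverage(mask, atlas, domain = domain, alpha = alpha)
  top <- top_parcels(cov, n = 15)
  # the parcel that best represents the effect region: largest fraction of
  # its own voxels inside the region
  lab_tab <- atlas$parcel_table$label
  in_reg <- tabulate(atlas$labels[sim$truth$effect_mask & atlas$labels > 0],
                     nbins = max(lab_tab))[lab_tab]
  size <- tabulate(atlas$labels[atlas$labels > 0],
                   nbins = max(lab_tab))[lab_tab]
  effect_label <- lab_tab[which.max(in_reg / pmax(size, 1))]
  list(sensitivity = rec$sensitivity, specificity = rec$specificity,
       n_significant = rec$n_significant,
       top_parcel_label = top$label[1],
       effect_parcel_label = effect_label,
       effect_parcel_rank = match(effect_label, top$label),
       top_is_effect_parcel = identical(as.integer(top$label[1]),
                                        as.integer(effect_label)),
       frac_affected_severe = mean(truth_ids %in% sev),
       fit = fit, coverage = cov, groups = groups, truth = sim$truth,
       atlas = atlas)
}
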