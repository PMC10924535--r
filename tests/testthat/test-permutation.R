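test_that("label permutations enumerate small designs and preserve sizes", {
  pl <- permute_labels(4, 2, k = 1000, seed = 1)
  expect_true(pl$exhaustive)
  expect_identical(pl$n_assignments, 6L)        # C(4,2) = 6
  expect_identical(ncol(pl$Z), 6L)
  expect_identical(unique(colSums(pl$Z)), 2)
  expect_identical(nrow(unique(t(pl$Z))), 6L)   # all distinct

  pl2 <- permute_labels(30, 11, k = 50, seed = 3, exhaustive_limit = 100)
  expect_false(pl2$exhaustive)
  expect_identical(dim(pl2$Z), c(30L, 50L))
  expect_identical(unique(colSums(pl2$Z)), 11)
  expect_identical(permute_labels(30, 11, 50, seed = 3,
                                  exhaustive_limit = 100)$Z, pl2$Z)
})

test_that("null summaries match a hand enumeration on a 2v2 toy cohort", {
  m <- rbind(c(0.9, 0.8, 0.1, 0.2),
             c(0.3, 0.5, 0.4, 0.6),
             c(0.7, 0.1, 0.6, 0.3))
  cohort <- cohort_from_matrix(m, d = c(3, 1, 1))
  groups <- vlsm_groups(cohort$subject_ids[1:2], cohort$subject_ids[3:4])
  for (mode in c("min_stat", "perm_percentile")) {
    cfg <- perm_config(mode = mode, n_permutations = 10)
    null <- build_null(cohort, groups, cfg)
    expect_true(null$exhaustive)
    expect_identical(null$n_permutations, 6L)
    oracle <- oracle_null_summaries(
      m, 2, mode = if (mode == "min_stat") "min" else "pct",
      percentile_q = 5)
    expect_equal(sort(null$summary_values), sort(oracle),
                 tolerance = 1e-10)
  }
  # order-statistic inequality: per-permutation min <= 5th percentile
  pl <- permute_labels(4, 2, 6)
  n_min <- build_null(cohort, groups, perm_config(mode = "min_stat"),
                      perms = pl)
  n_p5 <- build_null(cohort, groups,
                     perm_config(mode = "perm_percentile"), perms = pl)
  expect_true(all(n_min$summary_values <= n_p5$summary_values + 1e-12))

  # perfectly separating voxel: exhaustive min-stat p = 1/6
  p <- p_map_fwe(t_map(cohort, groups), n_min)
  expect_equal(p$values[1, 1, 1], 1 / 6)
})

test_that("single valid voxel makes the two null modes coincide", {
  m <- rbind(c(0.9, 0.7, 0.2, 0.1, 0.3, 0.0),
             rep(0, 6), rep(0, 6), rep(1, 6))
  cohort <- cohort_from_matrix(m, d = c(4, 1, 1))
  groups <- vlsm_groups(cohort$subject_ids[1:3], cohort$subject_ids[4:6])
  pl <- permute_labels(6, 3, 20)
  n_min <- build_null(cohort, groups, perm_config(mode = "min_stat"),
                      perms = pl)
  n_p5 <- build_null(cohort, groups,
                     perm_config(mode = "perm_percentile"), perms = pl)
  expect_equal(n_min$summary_values, n_p5$summary_values)
})

test_that("family-wise p counting follows the declared tail rules", {
  cohort <- random_cohort(6, d = c(4, 4, 4), seed = 31)
  groups <- vlsm_groups(cohort$subject_ids[1:3], cohort$subject_ids[4:6])
  obs <- t_map(cohort, groups)
  null <- structure(list(
    summary_values = c(-4, -3, -2, -1), mode = "min_stat",
    percentile_q = 5, n_permutations = 4L, exhaustive = FALSE,
    statistic = "t", group_sizes = unname(obs$group_sizes), seed = 1L),
    class = "null_distribution")
  fake <- obs
  fake$values[fake$valid][1:3] <- c(-10, 5, -2)  # below all / above all / tie
  p <- p_map_fwe(fake, null)
  pv <- p$values[fake$valid][1:3]
  expect_equal(pv[1], 1 / 5)    # Monte-Carlo floor (1+0... all 4 <= -10? no
  # -10 below every summary: count 0 -> (1+0)/5
  expect_equal(pv[2], 1)        # all summaries below +5 -> (1+4)/5
  expect_equal(pv[3], (1 + 3) / 5)  # ties count as extreme
  # provenance guards
  null$group_sizes <- c(2L, 4L)
  expect_error(p_map_fwe(fake, null), "group sizes")
})

test_that("per-voxel RR p-values match exhaustive enumeration on 3v3", {
  withr::with_seed(37, {
    m <- matrix(rbinom(20 * 6, 1, 0.5) * runif(120, 0.2, 1), 20, 6)
  })
  cohort <- cohort_from_matrix(m, d = c(20, 1, 1))
  groups <- vlsm_groups(cohort$subject_ids[1:3], cohort$subject_ids[4:6])
  cfg <- perm_config(n_permutations = 10, mode = "per_voxel")
  pm <- p_map_pervoxel(cohort, groups, cfg, statistic = "rr",
                       rr_threshold = 0.03)
  expect_true(pm$exhaustive)
  expect_identical(pm$n_permutations, 20L)      # C(6,3)
  oracle <- oracle_pervoxel_rr_p(m, 3, 0.03)
  got <- pm$values[cohort$space$brain_mask]
  idx <- !is.na(oracle)
  expect_equal(got[idx], unname(oracle[idx]), tolerance = 1e-12)
  expect_true(all(is.nan(got[!idx])))
  # p-values are multiples of 1/20
  expect_true(all(abs(got[idx] * 20 - round(got[idx] * 20)) < 1e-9))
  # all-ties voxel (constant RR across permutations) has p = 1
  const_idx <- which(apply(m >= 0.03, 1, function(r) all(r)))
  if (length(const_idx))
    expect_true(all(got[const_idx] == 1))
})

test_that("q-values implement Benjamini-Hochberg step-up", {
  space <- full_space(c(4, 1, 1))
  pm <- structure(list(
    values = array(c(0.01, 0.02, 0.03, 0.04), c(4, 1, 1)),
    valid = array(TRUE, c(4, 1, 1)), method = "per_voxel_perm",
    statistic = "relative_risk", group_sizes = c(3L, 3L), null = NULL,
    space = space), class = "pvalue_map")
  q <- q_values(pm)
  expect_equal(as.vector(q$values), rep(0.04, 4))
  # equal p: q equals p
  pm$values[] <- 0.2
  expect_equal(as.vector(q_values(pm)$values), rep(0.2, 4))
  # random vectors: agree with the textbook recipe, and q >= p
  withr::with_seed(41, {
    for (i in 1:5) {
      p <- runif(7)
      pm7 <- structure(list(values = array(p, c(7, 1, 1)),
                            valid = array(TRUE, c(7, 1, 1)),
                            method = "x", statistic = "t",
                            group_sizes = c(3L, 3L), null = NULL,
                            space = full_space(c(7, 1, 1))),
                       class = "pvalue_map")
      q <- as.vector(q_values(pm7)$values)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-12))
    }
  })
})

test_that("significance thresholding is strict and respects validity", {
  space <- full_space(c(3, 1, 1))
  pm <- structure(list(values = array(c(0.049, 0.05, NaN), c(3, 1, 1)),
                       valid = array(c(TRUE, TRUE, FALSE), c(3, 1, 1)),
                       method = "x", statistic = "t",
                       group_sizes = c(3L, 3L), null = NULL, space = space),
                  class = "pvalue_map")
  sig <- threshold_map(pm, 0.05)
  expect_identical(as.vector(sig$mask), c(TRUE, FALSE, FALSE))
  pm$valid[] <- FALSE
  expect_identical(sum(threshold_map(pm, 0.05)$mask), 0L)
  expect_error(threshold_map(pm, 1), "allowed range")
})

test_that("identical seeds give bit-identical p maps", {
  cohort <- random_cohort(10, d = c(5, 5, 5), seed = 43)
  groups <- vlsm_groups(cohort$subject_ids[1:5], cohort$subject_ids[6:10])
  cfg <- perm_config(n_permutations = 50, seed = 99, exhaustive_limit = 0)
  n1 <- build_null(cohort, groups, cfg)
  n2 <- build_null(cohort, groups, cfg)
  expect_identical(n1$summary_values, n2$summary_values)
  p1 <- p_map_pervoxel(cohort, groups, cfg, statistic = "rr")
  p2 <- p_map_pervoxel(cohort, groups, cfg, statistic = "rr")
  expect_identical(p1$values, p2$values)
})

test_that("parametric t p-values use the Student CDF", {
  cohort <- random_cohort(8, d = c(4, 4, 4), seed = 47)
  groups <- vlsm_groups(cohort$subject_ids[1:4], cohort$subject_ids[5:8])
  tm <- t_map(cohort, groups)
  p <- p_map_parametric(tm)
  expect_equal(p$values[tm$valid], pt(tm$values[tm$valid], df = 6),
               tolerance = 1e-12)
})
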