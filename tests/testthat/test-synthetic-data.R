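test_that("template mask is a deterministic ellipsoid of the stated size", {
  cfg <- sim_config(grid_shape = c(32, 32, 32))
  sp1 <- make_template(cfg)
  sp2 <- make_template(cfg)
  expect_identical(sp1$brain_mask, sp2$brain_mask)
  # semi-axes 0.45 * shape: extent along each axis ~ 0.9 * 32
  for (ax in 1:3) {
    extent <- range(which(apply(sp1$brain_mask, ax, any)))
    expect_equal(diff(extent) + 1, 29, tolerance = 0.05)
  }
  # occupancy matches the ellipsoid volume fraction 4/3*pi*0.45^3
  expect_equal(mean(sp1$brain_mask), 4 / 3 * pi * 0.45^3, tolerance = 0.02)
  expect_error(sim_config(grid_shape = c(8, 8, 8)), ">= 16")
})

test_that("voronoi atlas partitions the brain mask into non-empty parcels", {
  sp <- make_template(sim_config(grid_shape = c(20, 20, 20)))
  atlas <- make_atlas(sp, n_parcels = 24, seed = 5)
  labs <- atlas$labels[sp$brain_mask]
  expect_true(all(labs >= 1 & labs <= 24))
  expect_identical(sort(unique(labs)), 1:24)
  expect_identical(sum(tabulate(labs, 24)), sum(sp$brain_mask))
  expect_true(all(atlas$labels[!sp$brain_mask] == 0))
  expect_identical(make_atlas(sp, 24, seed = 5)$labels, atlas$labels)
  expect_false(identical(make_atlas(sp, 24, seed = 6)$labels, atlas$labels))
  expect_error(make_atlas(sp, n_parcels = sum(sp$brain_mask) + 1),
               "exceeds")
})

test_that("simulated cohorts are deterministic, fuzzy and mask-confined", {
  cfg <- sim_config(grid_shape = c(16, 16, 16), n_subjects = 12,
                    n_affected = 5, seed = 7)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$data, s2$cohort$data)
  expect_identical(s1$truth$centers, s2$truth$centers)
  expect_gte(min(s1$cohort$data), 0)
  expect_lte(max(s1$cohort$data), 1)
  expect_true(all(s1$cohort$data[!s1$cohort$space$brain_mask] == 0))
  # smoothing makes the masks fuzzy, not binary
  vals <- s1$cohort$data[s1$cohort$data > 0]
  expect_gt(mean(vals > 0 & vals < 1), 0.5)
  expect_identical(sum(s1$truth$affected), 5L)
})

test_that("effect_strength=1 pins affected lesion centres in the region", {
  cfg <- sim_config(grid_shape = c(16, 16, 16), n_subjects = 10,
                    n_affected = 5, effect_strength = 1,
                    lesion_radius_range = c(3, 3), seed = 9)
  s <- simulate_cohort(cfg)
  reg <- s$truth$effect_mask
  for (i in which(s$truth$affected)) {
    ctr <- s$truth$centers[i, ]
    expect_true(reg[ctr[1], ctr[2], ctr[3]])
  }
  # effect region must sit inside the mask
  bad <- sim_config(grid_shape = c(16, 16, 16),
                    effect_center = c(2, 2, 2), effect_radius = 3)
  expect_error(simulate_cohort(bad), "inside the brain mask")
})

test_that("separable gaussian smoothing matches a brute-force convolution", {
  set.seed(21)
  vol <- array(runif(6 * 6 * 6), c(6, 6, 6))
  sigma <- 1.2
  got <- vlsmap:::.gauss_smooth3d(vol, sigma)
  r <- ceiling(3 * sigma)
  off <- (-r):r
  k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expected <- array(0, dim(vol))
  for (x in 1:6) for (y in 1:6) for (z in 1:6) {
    acc <- 0
    for (i in seq_along(off)) for (j in seq_along(off))
      for (l in seq_along(off)) {
        xi <- x + off[i]; yj <- y + off[j]; zl <- z + off[l]
        if (xi >= 1 && xi <= 6 && yj >= 1 && yj <= 6 && zl >= 1 && zl <= 6)
          acc <- acc + k1[i] * k1[j] * k1[l] * vol[xi, yj, zl]
      }
    expected[x, y, z] <- acc
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("scores follow z = noise - deficit_shift * overlap", {
  cfg <- sim_config(grid_shape = c(16, 16, 16), n_subjects = 6,
                    n_affected = 3, score_noise_sd = 1e-12,
                    deficit_shift = 3, seed = 13)
  sp <- make_template(cfg)
  reg <- vlsmap:::.sphere_mask(sp$grid_shape, cfg$effect_center,
                               cfg$effect_radius)
  # subject 1: full overlap (prob 1 inside region); subject 2: none
  v1 <- array(0, sp$grid_shape); v1[reg] <- 1
  v2 <- array(0, sp$grid_shape); v2[2, 8, 8] <- 1
  vols <- c(list(v1, v2), replicate(4, v2 * 0.5, simplify = FALSE))
  cohort <- lesion_cohort(vols, sprintf("S%03d", 1:6), sp)
  truth <- structure(list(effect_mask = reg,
                          affected = setNames(rep(c(TRUE, FALSE), each = 3),
                                              cohort$subject_ids),
                          centers = matrix(8, 6, 3), radii = rep(3, 6),
                          config = cfg),
                     class = "ground_truth")
  scores <- simulate_scores(cohort, truth, cfg)
  s1 <- scores$z_score[scores$subject_id == "S001"]
  s2 <- scores$z_score[scores$subject_id == "S002"]
  expect_equal(unique(round(s1, 6)), -3)   # full overlap, shift 3
  expect_equal(unique(round(s2, 6)), 0)    # zero overlap -> z ~ 0
  expect_identical(scores$z_score,
                   simulate_scores(cohort, truth, cfg)$z_score)
  expect_identical(nrow(scores), 6L * 5L * 2L)
})

test_that("stronger planted effects mean more lesion mass in the region", {
  overlaps <- sapply(c(0, 0.5, 1), function(es) {
    mean(sapply(1:20, function(s) {
      cfg <- sim_config(grid_shape = c(16, 16, 16), n_subjects = 8,
                        n_affected = 4, effect_strength = es, seed = 100 + s)
      sim <- simulate_cohort(cfg)
      reg <- as.vector(sim$truth$effect_mask)
      flat <- matrix(sim$cohort$data, ncol = 8)
      mean(flat[reg, sim$truth$affected])
    }))
  })
  expect_true(all(diff(overlaps) > 0))
})

test_that("simulation configs load from YAML with validation", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sim.yaml")
  writeLines(c("grid_shape: [16, 16, 16]", "n_subjects: 12",
               "n_affected: 5", "seed: 9"), p)
  cfg <- sim_config_from_yaml(p)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$n_subjects, 12L)
  expect_identical(cfg$grid_shape, c(16L, 16L, 16L))
  writeLines(c("n_subjects: 12", "lesion_sizes: [1, 2]"), p)
  expect_error(sim_config_from_yaml(p), "unknown simulation config field")
})
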