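make_test_atlas <- function(seed = 5, d = c(16, 16, 16), n_parcels = 8) {
  sp <- make_template(sim_config(grid_shape = d))
  make_atlas(sp, n_parcels = n_parcels, seed = seed)
}

test_that("parcel coverage computes percentage involvement with conservation", {
  atlas <- make_test_atlas()
  sp <- atlas$space
  # deterministic partial mask: one parcel 100%, everything else 0
  sig <- atlas$labels == 3
  cov <- parcel_coverage(sig, atlas, domain = "memory", alpha = 0.05)
  expect_equal(cov$coverage_percent[cov$label == 3], 100)
  expect_equal(sum(cov$coverage_percent[!cov$label %in% c(0, 3)]), 0)
  expect_identical(cov$alpha_used[1], 0.05)

  # empty mask -> all zero; whole brain -> all 100
  cov0 <- parcel_coverage(array(FALSE, sp$grid_shape), atlas)
  expect_true(all(cov0$coverage_percent == 0))
  covf <- parcel_coverage(sp$brain_mask, atlas)
  expect_true(all(covf$coverage_percent[covf$label != 0] == 100))

  # conservation on random masks: sum of per-parcel counts equals
  # |sig ∩ labelled|, exactly
  withr::with_seed(53, {
    for (i in 1:5) {
      sig <- array(runif(prod(sp$grid_shape)) < 0.3, sp$grid_shape) &
        sp$brain_mask
      cv <- parcel_coverage(sig, atlas)
      expect_identical(sum(cv$significant_voxels[cv$label != 0]),
                       sum(sig & atlas$labels > 0))
      expect_identical(sum(cv$significant_voxels), sum(sig))
      expect_true(all(cv$significant_voxels <= cv$parcel_voxels))
    }
  })
  expect_error(parcel_coverage(array(FALSE, c(4, 4, 4)), atlas), "grid")
})

test_that("top parcels rank by coverage with declared tie-breaks", {
  cov <- data.frame(
    domain = "x", label = 1:4, parcel = paste0("p", 1:4),
    hemisphere = "L", class = "cortical",
    parcel_voxels = c(100, 200, 100, 50),
    significant_voxels = c(40, 80, 20, 30), alpha_used = 0.05)
  cov$coverage_percent <- 100 * cov$significant_voxels / cov$parcel_voxels
  class(cov) <- c("parcel_coverage", "data.frame")
  top <- top_parcels(cov, n = 15)   # n beyond count -> all parcels
  expect_identical(nrow(top), 4L)
  # label 4 leads at 60%; the 40% tie between labels 1 (size 100) and 2
  # (size 200) resolves to the larger parcel first
  expect_identical(top$label, c(4L, 2L, 1L, 3L))
  expect_true(all(diff(top$coverage_percent) <= 0))
  expect_identical(top_parcels(cov, n = 2)$label, c(4L, 2L))
})

test_that("heatmap matrix unions per-domain top parcels and orders rows", {
  atlas <- make_test_atlas(n_parcels = 6)
  sp <- atlas$space
  sig_a <- array(atlas$labels %in% c(1, 2), sp$grid_shape)
  sig_b <- array(atlas$labels %in% 5, sp$grid_shape)
  tabs <- list(memory = parcel_coverage(sig_a, atlas, "memory", 0.2),
               language = parcel_coverage(sig_b, atlas, "language", 0.2))
  hm <- heatmap_matrix(tabs, class_filter = "all", top_n = 2)
  expect_identical(colnames(hm), c("memory", "language"))
  # union of tops: 1,2 from memory, 5 (+ a zero parcel) from language
  expect_true(all(c(1L, 2L, 5L) %in% attr(hm, "labels")))
  expect_true(all(diff(apply(hm, 1, max)) <= 0))
  expect_equal(hm[match(5L, attr(hm, "labels")), "memory"], 0)

  # single domain: matrix equals its ranked coverage column
  hm1 <- heatmap_matrix(tabs["memory"], class_filter = "all", top_n = 6)
  ranked <- top_parcels(tabs$memory, 6)
  expect_equal(unname(hm1[, 1]),
               ranked$coverage_percent[match(attr(hm1, "labels"),
                                             ranked$label)])
  # all-zero domain column is retained
  tabs$none <- parcel_coverage(array(FALSE, sp$grid_shape), atlas,
                               "none", 0.2)
  hm2 <- heatmap_matrix(tabs, class_filter = "all", top_n = 2)
  expect_true(all(hm2[, "none"] == 0))
  # inconsistent atlases rejected
  other <- make_test_atlas(n_parcels = 5)
  tabs$bad <- parcel_coverage(array(FALSE, sp$grid_shape), other,
                              "bad", 0.2)
  expect_error(heatmap_matrix(tabs, class_filter = "all"), "inconsistent")
})

test_that("coverage grows monotonically with the alpha threshold", {
  cohort <- random_cohort(12, d = c(16, 16, 16), seed = 59,
                          space = make_test_atlas()$space)
  atlas <- make_test_atlas()
  groups <- vlsm_groups(cohort$subject_ids[1:6], cohort$subject_ids[7:12])
  fit <- vlsm(cohort, groups, inference = "per_voxel", statistic = "rr",
              n_permutations = 99, seed = 3, exhaustive_limit = 0)
  m05 <- threshold_map(fit$p, 0.05)
  m20 <- threshold_map(fit$p, 0.2)
  expect_true(all(m20$mask[m05$mask]))   # nested significant sets
  c05 <- parcel_coverage(m05, atlas)
  c20 <- parcel_coverage(m20, atlas)
  expect_true(all(c20$coverage_percent >= c05$coverage_percent))
})

test_that("atlases round-trip through NIfTI + CSV", {
  dir <- withr::local_tempdir()
  atlas <- make_test_atlas()
  save_atlas(atlas, file.path(dir, "atlas.nii.gz"),
             file.path(dir, "parcels.csv"))
  back <- load_atlas(file.path(dir, "atlas.nii.gz"),
                     file.path(dir, "parcels.csv"), atlas$space)
  expect_identical(back$labels, atlas$labels)
  expect_identical(back$parcel_table$name, atlas$parcel_table$name)
})
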