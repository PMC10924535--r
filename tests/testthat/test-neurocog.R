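test_that("z-score severity bands follow the clinical cutoffs", {
  expect_identical(grade_test(-2.5), "severe")
  expect_identical(grade_test(0.5), "normal")
  # band boundaries go to mild/moderate (conservative toward control)
  expect_identical(grade_test(c(-2, 0, -1.999, -0.0001)),
                   c("mild_moderate", "mild_moderate", "mild_moderate",
                     "mild_moderate"))
  expect_identical(grade_test(c(-10, 1e-9)), c("severe", "normal"))
  # subjective grades pass through; exactly one source per test
  expect_identical(grade_test(NA_real_, "severe"), "severe")
  expect_identical(grade_test(c(-3, NA), c(NA, "normal")),
                   c("severe", "normal"))
  expect_error(grade_test(-1, "normal"), "exactly one")
  expect_error(grade_test(NA_real_, NA_character_), "exactly one")
  expect_error(grade_test(Inf), "non-finite")
  expect_error(grade_test(NA_real_, "awful"), "unknown")
})

test_that("domain severity is the worst test result; affected iff severe", {
  expect_identical(assess_domain(c("severe", "normal")),
                   list(severity = "severe", group = "affected"))
  expect_identical(assess_domain(c("mild_moderate", "mild_moderate")),
                   list(severity = "mild_moderate", group = "control"))
  expect_identical(assess_domain(c("normal", "normal")),
                   list(severity = "normal", group = "control"))
  expect_identical(assess_domain(c("normal", "mild_moderate"))$group,
                   "control")
  expect_error(assess_domain(character(0)), "no test results")
})

test_that("groups partition the cohort and respect missing assessments", {
  scores <- data.frame(
    subject_id = rep(sprintf("P%02d", 1:6), each = 2),
    domain = "language",
    test_name = rep(c("t1", "t2"), 6),
    z_score = c(-3, 0.5,   -1, -0.5,   0.2, 1,   -2.6, -2.9,   -2, -2,
                0.1, -4))
  a <- assess_scores(scores)
  g <- build_groups(a, "language")
  expect_identical(g$affected, c("P01", "P04", "P06"))
  expect_identical(g$control, c("P02", "P03", "P05"))
  expect_identical(sort(c(g$affected, g$control)),
                   sprintf("P%02d", 1:6))   # partition property

  # cohort subject with no assessment row is an error
  expect_error(build_groups(a, "language",
                            subjects = sprintf("P%02d", 1:7)), "P07")
  # subject with no administered test in the domain: unassessable, excluded
  expect_warning(a2 <- assess_scores(scores[scores$subject_id != "P03", ],
                                     subjects = sprintf("P%02d", 1:6)),
                 "unassessable")
  expect_warning(g2 <- build_groups(a2, "language",
                                    subjects = sprintf("P%02d", 1:6)),
                 "excluding")
  expect_false("P03" %in% c(g2$affected, g2$control))
  # duplicated assessment rows are rejected
  expect_error(build_groups(rbind(a, a[1, ]), "language"), "duplicated")
})

test_that("worsening one test never moves a subject out of affected", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      z <- rnorm(4, -1, 1.5)
      base <- data.frame(subject_id = "X", domain = "memory",
                         test_name = paste0("t", 1:4), z_score = z)
      g0 <- assess_scores(base)$group
      worse <- base
      j <- sample.int(4, 1)
      worse$z_score[j] <- worse$z_score[j] - runif(1, 0, 5)
      g1 <- assess_scores(worse)$group
      if (g0 == "affected") expect_identical(g1, "affected")
    }
  })
})

test_that("score tables round-trip through the CSV interchange format", {
  dir <- withr::local_tempdir()
  scores <- data.frame(subject_id = c("A", "A"), domain = "memory",
                       test_name = c("t1", "t2"),
                       z_score = c(-2.5, NA),
                       subjective_grade = c(NA, "mild_moderate"))
  p <- file.path(dir, "scores.csv")
  write.csv(scores, p, row.names = FALSE)
  back <- read_scores(p)
  a <- assess_scores(back)
  expect_identical(a$severity, "severe")
  ap <- file.path(dir, "assess.csv")
  write_assessments(a, ap)
  expect_identical(read.csv(ap)$group, "affected")
})
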