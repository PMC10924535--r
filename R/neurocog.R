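# Neurocognitive grading: per-test severity bands, worst-test domain rule,
# and the severe-only affected/control grouping that drives all voxelwise
# statistics.

.severity_levels <- c("normal", "mild_moderate", "severe")

#' Grade a single test score into a severity band
#'
#' z-scores are banded as severe (z < -2), mild/moderate (-2 <= z <= 0) and
#' normal (z > 0). The band boundaries z = -2 and z = 0 are assigned to
#' mild/moderate: conservative toward the control group, so only clearly
#' severe deficits define "affected". Subjective grades (for tests without
#' standardized norms) pass through unchanged.
#'
#' @param z_score Numeric vector of z-scores (NA where a subjective grade is
#'   supplied instead).
#' @param subjective_grade Character vector of `"normal"`,
#'   `"mild_moderate"`, `"severe"` (NA where `z_score` is supplied).
#' @return Character vector of severity bands.
#' @export
grade_test <- function(z_score, subjective_grade = NULL) {
  n <- max(length(z_score), length(subjective_grade))
  if (is.null(subjective_grade)) subjective_grade <- rep(NA_character_, n)
  if (length(z_score) == 0L) z_score <- rep(NA_real_, n)
  has_z <- !is.na(z_score)
  has_g <- !is.na(subjective_grade) & nzchar(subjective_grade)
  if (any(has_z == has_g))
    .stop_validation(
      "each test needs exactly one of z_score / subjective_grade")
  if (any(!is.finite(z_score[has_z])))
    .stop_validation("non-finite z_score")
  bad <- has_g & !(subjective_grade %in% .severity_levels)
  if (any(bad))
    .stop_validation("unknown subjective grade: %s",
                     paste(unique(subjective_grade[bad]), collapse = ", "))
  out <- character(n)
  out[has_z] <- ifelse(z_score[has_z] < -2, "severe",
                       ifelse(z_score[has_z] <= 0, "mild_moderate", "normal"))
  out[has_g] <- subjective_grade[has_g]
  out
}

#' Assess one subject-domain from its test results
#'
#' Domain severity is the worst (most impaired) severity among the domain's
#' tests, ordered normal < mild/moderate < severe; the domain is "affected"
#' if and only if that worst severity is severe — all lesser deficits go to
#' the control group.
#'
#' @param severities Character vector of per-test severity bands
#'   (from [grade_test()]); must be non-empty.
#' @return List with `severity` and `group` (`"affected"`/`"control"`).
#' @export
assess_domain <- function(severities) {
  if (length(severities) == 0L)
    .stop_validation("no test results for this domain")
  if (!all(severities %in% .severity_levels))
    .stop_validation("unknown severity: %s",
                     paste(setdiff(severities, .severity_levels),
                           collapse = ", "))
  worst <- .severity_levels[max(match(severities, .severity_levels))]
  list(severity = worst,
       group = if (worst == "severe") "affected" else "control")
}

#' Assess all subjects and domains from a score table
#'
#' Applies [grade_test()] and [assess_domain()] across a long score table.
#' Subjects listed in `subjects` but lacking any administered test for a
#' domain are reported as unassessable (severity NA) with a warning; they
#' are excluded from that domain's grouping by [build_groups()].
#'
#' @param scores data.frame with columns `subject_id`, `domain`,
#'   `test_name`, and `z_score` and/or `subjective_grade` (exactly one
#'   non-missing per row).
#' @param subjects Optional character vector of the full cohort's ids.
#' @return data.frame: `subject_id`, `domain`, `severity`, `group`.
#' @export
assess_scores <- function(scores, subjects = NULL) {
  need <- c("subject_id", "domain", "test_name")
  if (!all(need %in% names(scores)))
    .stop_validation("score table must have columns %s",
                     paste(need, collapse = ", "))
  if (is.null(scores$z_score)) scores$z_score <- NA_real_
  if (is.null(scores$subjective_grade))
    scores$subjective_grade <- NA_character_
  scores$severity <- grade_test(scores$z_score, scores$subjective_grade)
  key <- interaction(scores$subject_id, scores$domain, drop = TRUE)
  parts <- split(scores, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    a <- assess_domain(p$severity)
    data.frame(subject_id = p$subject_id[1], domain = p$domain[1],
               severity = a$severity, group = a$group,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(subjects)) {
    doms <- unique(out$domain)
    full <- expand.grid(subject_id = as.character(subjects), domain = doms,
                        stringsAsFactors = FALSE)
    merged <- merge(full, out, by = c("subject_id", "domain"), all.x = TRUE)
    missing <- is.na(merged$severity)
    if (any(missing)) {
      warning(sprintf(
        "%d subject-domain pairs have no administered tests; unassessable",
        sum(missing)), call. = FALSE)
    }
    out <- merged
  }
  out[order(out$domain, out$subject_id), , drop = FALSE]
}

#' Build the affected/control grouping for one domain
#'
#' Partitions subject ids into the affected group (severe deficit in the
#' domain) and the control group (everyone else). Unassessable subjects
#' (severity NA) are excluded with a warning; a cohort subject with no
#' assessment row at all is an error.
#'
#' @param assessments Output of [assess_scores()].
#' @param domain Domain identifier.
#' @param subjects Optional full cohort id vector to validate completeness.
#' @return Object of class `vlsm_groups`: list with character vectors
#'   `affected` and `control` and the `domain`.
#' @export
build_groups <- function(assessments, domain, subjects = NULL) {
  a <- assessments[assessments$domain == domain, , drop = FALSE]
  if (nrow(a) == 0L) .stop_validation("no assessments for domain `%s`", domain)
  if (anyDuplicated(a$subject_id))
    .stop_validation("duplicated assessment for subject(s): %s",
                     paste(unique(a$subject_id[duplicated(a$subject_id)]),
                           collapse = ", "))
  if (!is.null(subjects)) {
    miss <- setdiff(as.character(subjects), a$subject_id)
    if (length(miss))
      .stop_validation("subjects missing an assessment for `%s`: %s", domain,
                       paste(miss, collapse = ", "))
    a <- a[a$subject_id %in% as.character(subjects), , drop = FALSE]
  }
  unassessable <- is.na(a$severity)
  if (any(unassessable)) {
    warning(sprintf("excluding %d unassessable subject(s) from domain `%s`",
                    sum(unassessable), domain), call. = FALSE)
    a <- a[!unassessable, , drop = FALSE]
  }
  structure(list(
    affected = sort(a$subject_id[a$group == "affected"]),
    control = sort(a$subject_id[a$group == "control"]),
    domain = domain
  ), class = "vlsm_groups")
}

#' Construct a grouping directly from id vectors
#'
#' @param affected,control Disjoint character vectors of subject ids.
#' @param domain Optional domain tag.
#' @return A `vlsm_groups` object.
#' @export
vlsm_groups <- function(affected, control, domain = NA_character_) {
  affected <- as.character(affected); control <- as.character(control)
  if (length(intersect(affected, control)))
    .stop_validation("affected and control groups overlap")
  if (anyDuplicated(c(affected, control)))
    .stop_validation("duplicated subject id in groups")
  structure(list(affected = affected, control = control, domain = domain),
            class = "vlsm_groups")
}

#' @export
print.vlsm_groups <- function(x, ...) {
  cat(sprintf("Groups%s: %d affected vs %d control\n",
              if (is.na(x$domain)) "" else sprintf(" [%s]", x$domain),
              length(x$affected), length(x$control)))
  invisible(x)
}

# Logical affected-indicator in cohort subject order.
.group_indicator <- function(cohort, groups) {
  ids <- cohort$subject_ids
  unknown <- setdiff(c(groups$affected, groups$control), ids)
  if (length(unknown))
    .stop_validation("group subject(s) not in cohort: %s",
                     paste(unknown, collapse = ", "))
  ind <- ids %in% groups$affected
  keep <- ids %in% c(groups$affected, groups$control)
  list(affected = ind, in_groups = keep)
}

#' Read / write the neurocognitive CSV interchange tables
#'
#' `read_scores()` reads a long test-score table (`subject_id, domain,
#' test_name, z_score, subjective_grade`); `write_assessments()` writes the
#' per-subject per-domain assessment table.
#'
#' @param path CSV path.
#' @return `read_scores()`: a data.frame of scores.
#' @export
read_scores <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(s$subjective_grade))
    s$subjective_grade[s$subjective_grade == ""] <- NA_character_
  s
}

#' @rdname read_scores
#' @param assessments Output of [assess_scores()].
#' @export
write_assessments <- function(assessments, path) {
  write.csv(assessments, path, row.names = FALSE)
  invisible(path)
}
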