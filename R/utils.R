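# Internal helpers: argument checking, seed management, small utilities.

.stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          integer = FALSE, open_lower = FALSE,
                          open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stop_validation("`%s` must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    .stop_validation("`%s` = %g is outside its allowed range", name, x)
  if (integer && x != round(x))
    .stop_validation("`%s` must be an integer", name)
  x
}

# Stage-specific 32-bit seeds derived from one user seed, so that pipeline
# stages (simulation, scores, atlas, permutations) consume independent,
# individually reproducible streams.
.derive_seed <- function(seed, stage) {
  codes <- c(cohort = 101L, scores = 211L, atlas = 307L, perm = 401L,
             pipeline = 503L)
  code <- codes[[stage]]
  as.integer((as.numeric(seed) %% 2147480000 * 31 + code) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Voxel index grid (three V-length vectors) for a grid shape.
.voxel_grid <- function(dim) {
  list(
    x = rep.int(seq_len(dim[1]), times = dim[2] * dim[3]),
    y = rep.int(rep(seq_len(dim[2]), each = dim[1]), times = dim[3]),
    z = rep(seq_len(dim[3]), each = dim[1] * dim[2])
  )
}

.same_grid <- function(a, b) identical(as.integer(a), as.integer(b))

# Write an R object as canonical, order-stable JSON (no timestamps).
.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

.md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
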