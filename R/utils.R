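#' @keywords internal
"_PACKAGE"

# Derive a child seed from a master seed and an operation tag, so that the
# random stream of each pipeline stage is independent of the others and
# adding a stage does not perturb the rest.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 1000003
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row/column indices of the upper triangle, one row per unordered pair,
# ordered (1,2), (1,3), ..., matching m[upper.tri(m)].
pair_index <- function(n) {
  j <- rep(seq_len(n), each = n)[upper.tri(diag(n))]
  i <- rep(seq_len(n), times = n)[upper.tri(diag(n))]
  cbind(i = i, j = j)
}

upper_vec <- function(m) m[upper.tri(m)]

# Euclidean distance matrix between rows of xyz (an n x 3 matrix), in mm.
euclid_matrix <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

stop_if_not_symmetric <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-10, check.attributes = FALSE))) {
    stop(sprintf("%s must be a symmetric square matrix", what), call. = FALSE)
  }
  invisible(TRUE)
}
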