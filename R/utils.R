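# Internal helpers shared across modules.

# Stop unless a scalar condition holds; used for precondition checks.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# Names of the per-fraction abundance columns of a profile table.
fraction_cols <- function(x) {
  grep("^fraction_[0-9]+$", names(x), value = TRUE)
}

# Integer number of fractions encoded in the column names.
n_fractions <- function(x) length(fraction_cols(x))

# feature x fraction numeric matrix from a profile-table-like data frame.
fraction_matrix <- function(x) {
  m <- as.matrix(x[, fraction_cols(x), drop = FALSE])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

# Row-normalize a non-negative matrix so each row sums to 1. Zero rows kept as
# zero (callers decide whether to drop them).
row_normalize <- function(m) {
  s <- rowSums(m)
  nz <- s > 0
  m[nz, ] <- m[nz, , drop = FALSE] / s[nz]
  m
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# All pairwise cosine similarities between the rows of a matrix.
pairwise_cosine <- function(m) {
  n <- nrow(m)
  out <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) out[i, j] <- out[j, i] <- cosine_similarity(m[i, ], m[j, ])
    }
  }
  out
}

# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
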