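#' Construct a fraction profile table
#'
#' The central quantitative container: one row per feature x condition x
#' replicate, with one abundance column per gradient fraction
#' (`fraction_1` ... `fraction_F`). Two attributes track provenance:
#' `level` ("transcript" or "gene") and `state`, which records how far along
#' the normalization path the abundances are:
#' \describe{
#'   \item{raw}{library-relative quantifications (TPM/CPM scale).}
#'   \item{content_adjusted}{multiplied by the per-fraction RNA content.}
#'   \item{row_normalized}{each feature x replicate row sums to 1.}
#' }
#'
#' @param x data frame with columns `feature_id`, `biotype`, `condition`,
#'   `replicate` and `fraction_1..fraction_F`.
#' @param level "transcript" or "gene".
#' @param state normalization state flag.
#' @return a `gradloc_profiles` tibble.
#' @export
profile_table <- function(x, level = c("transcript", "gene"),
                          state = c("raw", "content_adjusted", "row_normalized")) {
  level <- match.arg(level)
  state <- match.arg(state)
  x <- tibble::as_tibble(x)
  needed <- c("feature_id", "biotype", "condition", "replicate")
  missing_cols <- setdiff(needed, names(x))
  assert_that(length(missing_cols) == 0,
              paste0("profile table lacks columns: ",
                     paste(missing_cols, collapse = ", ")))
  fc <- fraction_cols(x)
  assert_that(length(fc) >= 2, "profile table needs >= 2 fraction columns")
  m <- as.matrix(x[, fc])
  assert_that(all(is.finite(m)) && all(m >= 0),
              "fraction abundances must be finite and non-negative")
  if (state == "row_normalized") {
    s <- rowSums(m)
    assert_that(all(abs(s - 1) < 1e-9),
                "row_normalized state requires every row to sum to 1")
  }
  structure(x, class = c("gradloc_profiles", class(x)),
            level = level, state = state)
}

profile_state <- function(x) attr(x, "state") %||% "raw"
profile_level <- function(x) attr(x, "level") %||% "transcript"

# Rebuild attributes after dplyr verbs strip them.
restamp_profiles <- function(x, template, state = profile_state(template)) {
  profile_table(x, level = profile_level(template), state = state)
}

#' @export
print.gradloc_profiles <- function(x, ...) {
  cat(sprintf("<gradloc_profiles> %s-level, state: %s, %d fractions, %d rows\n",
              profile_level(x), profile_state(x), n_fractions(x), nrow(x)))
  NextMethod()
}

#' Write / read a profile table as TSV
#'
#' Plain TSV with the level and state flags stored in a `#` header line, so a
#' round trip preserves the normalization state.
#'
#' @param x a `gradloc_profiles` table.
#' @param path file path.
#' @export
write_profile_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gradloc_profiles level=%s state=%s",
                     profile_level(x), profile_state(x)), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_table
#' @param path file path.
#' @export
read_profile_table <- function(path) {
  header <- readLines(path, n = 1)
  level <- sub(".*level=(\\S+).*", "\\1", header)
  state <- sub(".*state=(\\S+).*", "\\1", header)
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  profile_table(x, level = level, state = state)
}

#' Mean fraction profile per feature
#'
#' Averages a row-normalized profile table across replicates within one
#' condition and returns a feature x fraction matrix (rows re-normalized to
#' sum 1).
#'
#' @param profiles a row-normalized `gradloc_profiles` table.
#' @param condition condition to average within; default: first present.
#' @return feature x fraction matrix.
#' @export
mean_feature_profiles <- function(profiles, condition = NULL) {
  assert_that(profile_state(profiles) == "row_normalized",
              "profiles must be row_normalized")
  cond <- condition %||% profiles$condition[1]
  x <- profiles[profiles$condition == cond, , drop = FALSE]
  assert_that(nrow(x) > 0, sprintf("no rows for condition '%s'", cond))
  fc <- fraction_cols(x)
  agg <- x |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(fc), mean), .groups = "drop")
  m <- as.matrix(agg[, fc])
  rownames(m) <- agg$feature_id
  row_normalize(m)
}
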