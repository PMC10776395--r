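#' Generate localization archetype profiles
#'
#' Builds one unimodal density-gradient profile per localization: triangular
#' bumps over the fraction index with peaks spread evenly across the gradient,
#' mimicking the way marker classes occupy distinct density bands. Rows are
#' normalized to sum 1 and are guaranteed mutually distinct (pairwise cosine
#' similarity < 0.95). When the gradient has more fractions than
#' localizations, peak positions receive a small seeded jitter so repeated
#' calls with different seeds explore slightly different gradients.
#'
#' @param localizations character vector of localization names (>= 2).
#' @param fraction_count number of gradient fractions (>= number of
#'   localizations, >= 2).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return a `gradloc_archetypes` object: list with `localizations`,
#'   `profiles` (localization x fraction matrix) and `fraction_count`.
#' @examples
#' ark <- generate_archetypes(c("nucleus", "cytosol"), 2, seed = 1)
#' ark$profiles
#' @export
generate_archetypes <- function(localizations, fraction_count, seed = 1L) {
  assert_that(is.character(localizations) && length(localizations) >= 2,
              "need at least 2 localization names")
  assert_that(!anyDuplicated(localizations),
              "localization names must be unique")
  assert_that(is.numeric(fraction_count) && fraction_count >= 2,
              "invalid config: fraction_count must be >= 2")
  assert_that(fraction_count >= length(localizations),
              "invalid config: fraction_count must be >= number of localizations")
  n_loc <- length(localizations)
  f <- seq_len(fraction_count)

  peaks <- seq(1, fraction_count, length.out = n_loc)
  spacing <- if (n_loc > 1) (fraction_count - 1) / (n_loc - 1) else 1
  slack <- (fraction_count - n_loc) / max(1, n_loc)
  # Real gradients band: localizations cluster in pairs within shared density
  # bands (nucleolus with nucleus, ER with mitochondria, ...) with empty
  # stretches of gradient between bands. When the gradient has slack, pull
  # consecutive pairs toward their shared band center; this also keeps the
  # constant vector out of the basis row span, which is what makes the
  # deconvolution intercept identifiable.
  if (fraction_count > n_loc && n_loc >= 4) {
    for (i in seq(1, n_loc - 1, by = 2)) {
      mid <- mean(peaks[c(i, i + 1)])
      half <- 0.2 * spacing
      peaks[i] <- mid - half
      peaks[i + 1] <- mid + half
    }
  }
  rand <- with_seed(seed, runif(2 * n_loc, -1, 1))
  peaks <- peaks + rand[seq_len(n_loc)] * min(0.15, slack / 3)
  peaks <- pmin(pmax(peaks, 1), fraction_count)
  # half-width at most the peak spacing: bumps overlap within a band but each
  # class peaks where the others have decayed
  widths <- spacing * (0.55 + 0.25 * (seq_len(n_loc) %% 2) +
                         0.05 * rand[n_loc + seq_len(n_loc)])
  widths <- pmin(widths, spacing)

  # low-level smear across the whole gradient (diffusion between bands), so
  # no fraction is ever completely empty; only meaningful when the gradient
  # has slack between bands
  baseline <- if (fraction_count > n_loc) 0.02 else 0
  profiles <- t(vapply(seq_len(n_loc), function(i) {
    bump <- pmax(0, 1 - abs(f - peaks[i]) / widths[i])
    bump <- (1 - baseline) * bump / sum(bump) + baseline / fraction_count
    bump / sum(bump)
  }, numeric(fraction_count)))
  dimnames(profiles) <- list(localizations, paste0("fraction_", f))

  cs <- pairwise_cosine(profiles)
  diag(cs) <- 0
  assert_that(max(cs) < 0.95,
              "archetype profiles are not distinct enough (cosine >= 0.95)")
  structure(list(localizations = localizations, profiles = profiles,
                 fraction_count = as.integer(fraction_count)),
            class = "gradloc_archetypes")
}

#' @export
print.gradloc_archetypes <- function(x, ...) {
  cat(sprintf("<gradloc_archetypes> %d localizations x %d fractions\n",
              length(x$localizations), x$fraction_count))
  print(round(x$profiles, 3))
  invisible(x)
}
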