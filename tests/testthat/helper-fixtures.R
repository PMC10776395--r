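# Shared fixtures, built in code at test time.

six_locs <- c("nucleus", "nucleolus", "cytosol", "cytosol_light", "er",
              "mitochondria")

test_archetypes <- function(seed = 1) generate_archetypes(six_locs, 8, seed)

# A small noisy dataset shared across test files (built once per run).
.small_ds_cache <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.small_ds_cache$ds)) {
    cfg <- sim_config(n_transcripts = 400, n_markers_per_class = 10, seed = 3)
    .small_ds_cache$ds <- simulate_rna_experiment(cfg, test_archetypes())
  }
  .small_ds_cache$ds
}

# Minimal profile table: one feature per row of `m`, single replicate.
toy_profile_table <- function(m, condition = "control", replicate = 1L,
                              biotype = "mRNA", state = "raw") {
  colnames(m) <- paste0("fraction_", seq_len(ncol(m)))
  profile_table(
    tibble::tibble(feature_id = rownames(m) %||% sprintf("F%02d", seq_len(nrow(m))),
                   biotype = biotype, condition = condition,
                   replicate = replicate,
                   tibble::as_tibble(m, .name_repair = "minimal")),
    state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force grid oracle for the 2-basis-row + intercept NNLS problem.
grid_nnls_oracle <- function(y, basis, p_max = 1.5, c_max = 0.5, step = 0.01) {
  ps <- seq(0, p_max, by = step)
  cs <- seq(-c_max, c_max, by = step)
  best <- list(sse = Inf)
  for (p1 in ps) {
    r1 <- y - p1 * basis[1, ]
    for (p2 in ps) {
      r2 <- r1 - p2 * basis[2, ]
      for (cc in cs) {
        sse <- sum((r2 - cc)^2)
        if (sse < best$sse) best <- list(sse = sse, p = c(p1, p2), c = cc)
      }
    }
  }
  best
}
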