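#' Simulate a density-gradient RNA fractionation experiment
#'
#' Generates an experiment with known ground truth: transcripts with
#' biotype-dependent localization proportion vectors (markers are pure
#' single-localization anchors), per-fraction expected abundances
#' `abundance x (proportions . archetypes) x content x library factor`,
#' negative-binomial counting noise, spike-in features at a fixed absolute
#' amount per fraction (added before library scaling), and an
#' mRNA-specific logistic relocalization to granules in the stress condition.
#'
#' Quantifications are reported on the TPM scale over endogenous transcripts;
#' spike-in totals per library are carried separately in the returned
#' `spikeins` table so the content adjustment can be recomputed downstream.
#'
#' @param config a [sim_config()] object.
#' @param archetypes a [generate_archetypes()] object over
#'   `config$localizations`.
#' @return a `gradloc_dataset` list with elements `rna_profiles` (raw-state
#'   [profile_table()]), `spikeins` (per-library spike totals and proportion
#'   used), `true_proportions` (feature x condition x localization),
#'   `feature_table` (length, AU content, biotype, UTR/CDS lengths, marker
#'   flags), `rbp_binding` (binary feature x RBP tibble), `sequences` (named
#'   character), `markers` (marker-set tibble), `counts` (per-library count
#'   matrices, named `<condition>_<replicate>`) and the `config`/`archetypes`
#'   used.
#' @export
simulate_rna_experiment <- function(config, archetypes) {
  assert_that(inherits(config, "gradloc_sim_config"), "config must come from sim_config()")
  assert_that(inherits(archetypes, "gradloc_archetypes"),
              "archetypes must come from generate_archetypes()")
  assert_that(archetypes$fraction_count == config$fraction_count,
              "archetype fraction count does not match config")
  assert_that(identical(archetypes$localizations, config$localizations),
              "archetype localizations do not match config")
  with_seed(config$seed, simulate_rna_impl(config, archetypes))
}

simulate_rna_impl <- function(config, archetypes) {
  locs <- config$localizations
  n_loc <- length(locs)
  Fn <- config$fraction_count
  A <- archetypes$profiles

  ## ---- features: markers first, then biotype-sampled background ----
  n_marker <- config$n_markers_per_class * n_loc
  assert_that(config$n_transcripts > n_marker,
              "n_transcripts must exceed the number of simulated markers")
  n_bg <- config$n_transcripts - n_marker
  ids <- sprintf("TX%05d", seq_len(config$n_transcripts))
  marker_class <- c(rep(locs, each = config$n_markers_per_class),
                    rep(NA_character_, n_bg))
  is_marker <- !is.na(marker_class)
  biotype <- character(config$n_transcripts)
  # markers are mRNAs except the nucleolus anchors, which are snoRNAs (small
  # nucleolar RNAs are the field's nucleolar markers)
  biotype[is_marker] <- ifelse(marker_class[is_marker] == "nucleolus",
                               "snoRNA", "mRNA")
  biotype[!is_marker] <- sample(names(config$biotype_proportions), n_bg,
                                replace = TRUE,
                                prob = config$biotype_proportions)

  len <- pmin(30000, pmax(200, round(rlnorm(config$n_transcripts,
                                            meanlog = log(1500), sdlog = 0.6))))
  au <- stats::rbeta(config$n_transcripts, 5, 5) * 0.5 + 0.25
  abundance <- rlnorm(config$n_transcripts, config$abundance_meanlog,
                      config$abundance_sdlog)

  ## ---- ground-truth proportions, control condition ----
  p_control <- matrix(0, config$n_transcripts, n_loc,
                      dimnames = list(ids, locs))
  for (l in seq_len(n_loc)) {
    p_control[which(marker_class == locs[l]), l] <- 1
  }
  bg <- which(!is_marker)
  for (bt in unique(biotype[bg])) {
    rows <- bg[biotype[bg] == bt]
    alpha <- config$dirichlet_concentrations[[bt]]
    if (is.null(alpha)) alpha <- config$dirichlet_concentrations[["mRNA"]]
    p_control[rows, ] <- rdirichlet(length(rows), alpha)
  }

  ## ---- stress-condition truth: logistic granule gain for mRNAs ----
  truth <- list()
  truth[[config$conditions[1]]] <- p_control
  if (length(config$conditions) >= 2) {
    for (cond in config$conditions[-1]) {
      truth[[cond]] <- relocalize_truth(p_control, biotype, is_marker, len, au,
                                        locs, config$relocalization)
    }
  }

  ## ---- expected absolute amounts and noisy libraries ----
  spike_ids <- sprintf("SIRV%03d", seq_len(config$n_spikeins))
  spike_w <- rlnorm(config$n_spikeins, 0, 0.5)
  profiles <- list()
  spike_rows <- list()
  counts_out <- list()
  for (cond in config$conditions) {
    m <- truth[[cond]] %*% A                      # transcript x fraction mixing
    x_abs <- (abundance * m) * rep(config$content, each = nrow(m))
    input <- sweep(x_abs, 2, config$proportion_used, "*")
    endo_totals <- colSums(input)
    # spike-ins at one fixed absolute amount per fraction, scaled to the
    # configured share of a typical library input
    s_share <- config$spikein_fraction_of_library
    spike_total_abs <- if (s_share > 0) {
      s_share / (1 - s_share) * mean(endo_totals)
    } else {
      0
    }
    spike_abs <- spike_w / sum(spike_w) * spike_total_abs
    for (rep_i in seq_len(config$replicates)) {
      depth <- config$library_size *
        rlnorm(Fn, -config$library_size_sd^2 / 2, config$library_size_sd)
      all_abs <- rbind(input, matrix(spike_abs, config$n_spikeins, Fn,
                                     dimnames = list(spike_ids, colnames(input))))
      frac_share <- sweep(all_abs, 2, colSums(all_abs), "/")
      mu <- sweep(frac_share, 2, depth, "*")
      counts <- if (config$dispersion > 0) {
        matrix(rnbinom(length(mu), mu = as.vector(mu),
                       size = 1 / config$dispersion),
               nrow = nrow(mu), dimnames = dimnames(mu))
      } else {
        mu
      }
      tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
      endo_tpm <- tpm[ids, , drop = FALSE]
      # report endogenous quantifications renormalized to the endogenous
      # pool, with spike totals rescaled to the same per-million scale so the
      # endogenous:spike-in ratio of each library is preserved
      endo_tot <- colSums(endo_tpm)
      spike_tot <- colSums(tpm[spike_ids, , drop = FALSE]) / endo_tot * 1e6
      endo_tpm <- sweep(endo_tpm, 2, endo_tot, "/") * 1e6
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        feature_id = ids, biotype = biotype, condition = cond,
        replicate = rep_i,
        tibble::as_tibble(endo_tpm, .name_repair = "minimal")
      )
      counts_out[[paste(cond, rep_i, sep = "_")]] <- counts
      spike_rows[[length(spike_rows) + 1]] <- tibble::tibble(
        condition = cond, replicate = rep_i, fraction = seq_len(Fn),
        spikein_total = unname(spike_tot),
        proportion_used = config$proportion_used
      )
    }
  }
  rna_profiles <- profile_table(dplyr::bind_rows(profiles), "transcript", "raw")
  spikeins <- dplyr::bind_rows(spike_rows)

  true_proportions <- dplyr::bind_rows(lapply(names(truth), function(cond) {
    tibble::tibble(feature_id = ids, condition = cond,
                   tibble::as_tibble(truth[[cond]], .name_repair = "minimal"))
  }))

  ## ---- sequence and annotation features ----
  sequences <- simulate_sequences(ids, len, au)
  utr5 <- ifelse(biotype == "mRNA", pmax(12L, round(0.1 * len)), NA_integer_)
  cds <- ifelse(biotype == "mRNA",
                pmax(30L, (round(0.5 * len) %/% 3L) * 3L), NA_integer_)
  utr3 <- ifelse(biotype == "mRNA", pmax(0L, len - utr5 - cds), NA_integer_)

  feature_table <- tibble::tibble(
    feature_id = ids, biotype = biotype, length = len, au_content = au,
    abundance = abundance, utr5_length = as.integer(utr5),
    cds_length = as.integer(cds), utr3_length = as.integer(utr3),
    is_marker = is_marker, marker_class = marker_class
  )

  rbp_names <- sprintf("RBP%02d", seq_len(config$n_rbps))
  rbp <- matrix(rbinom(config$n_transcripts * config$n_rbps, 1,
                       config$rbp_binding_rate),
                config$n_transcripts, config$n_rbps,
                dimnames = list(ids, rbp_names))
  rbp_binding <- tibble::tibble(feature_id = ids,
                                tibble::as_tibble(rbp, .name_repair = "minimal"))

  markers <- tibble::tibble(
    member_id = ids[is_marker],
    localization = marker_class[is_marker],
    provenance = "apriori"
  )

  structure(list(rna_profiles = rna_profiles, spikeins = spikeins,
                 true_proportions = true_proportions,
                 feature_table = feature_table, rbp_binding = rbp_binding,
                 sequences = sequences, markers = markers,
                 counts = counts_out,
                 config = config, archetypes = archetypes),
            class = "gradloc_dataset")
}

# Move mass from cytosol/ER into the granule (cytosol-light) class for mRNAs,
# with gain expit(b0 + b1 log10 length + b2 AU + b3 membrane-prior). Markers
# stay put: they are the definitional anchors of their class.
relocalize_truth <- function(p, biotype, is_marker, len, au, locs, b) {
  granule <- intersect("cytosol_light", locs)
  movable <- intersect(c("cytosol", "er"), locs)
  membrane <- intersect(c("er", "mitochondria"), locs)
  if (length(granule) == 0 || length(movable) == 0) return(p)
  out <- p
  idx <- which(biotype == "mRNA" & !is_marker)
  if (length(idx) == 0) return(out)
  prior <- rowSums(p[idx, membrane, drop = FALSE])
  gain <- plogis(b[["intercept"]] + b[["log_length"]] * log10(len[idx]) +
                 b[["au_content"]] * au[idx] + b[["membrane_prior"]] * prior)
  moved <- gain * rowSums(p[idx, movable, drop = FALSE])
  mov <- p[idx, movable, drop = FALSE]
  mov_scaled <- mov * (1 - gain)
  out[idx, movable] <- mov_scaled
  out[idx, granule] <- p[idx, granule] + moved
  out
}

simulate_sequences <- function(ids, len, au) {
  seqs <- vapply(seq_along(ids), function(i) {
    probs <- c(A = au[i] / 2, U = au[i] / 2,
               G = (1 - au[i]) / 2, C = (1 - au[i]) / 2)
    paste(sample(names(probs), len[i], replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, ids)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the profile table, spike-in table, truth tables and FASTA sequences
#' under a directory, in the same formats the analysis functions read.
#'
#' @param dataset a `gradloc_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_table(dataset$rna_profiles, file.path(dir, "rna_profiles.tsv"))
  write.table(dataset$spikeins, file.path(dir, "spikeins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$true_proportions, file.path(dir, "true_proportions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$feature_table, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$markers, file.path(dir, "markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(paste0(">", names(dataset$sequences), "\n", dataset$sequences),
             fasta)
  invisible(dir)
}
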