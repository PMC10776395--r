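#' Simulate a PSM-level TMT quantification table
#'
#' Emulates a Proteome Discoverer-style export for a density-gradient
#' proteomics run: several PSMs per protein whose reporter-ion profile follows
#' the protein's localization archetype, log-normal PSM-level noise, planted
#' cRAP contaminants, endogenous proteins sharing an observed peptide with a
#' cRAP protein, displaced outlier PSMs (alien localization profile, so their
#' median profile distance to sibling PSMs exceeds the removal threshold), and
#' intensity-dependent missingness (left-censoring). Every plant is recorded
#' in the returned truth labels.
#'
#' At most one outlier is planted per protein and only in proteins with at
#' least four PSMs, so that on a noiseless table the outlier rule removes
#' exactly the planted PSMs.
#'
#' @param config a [sim_config()] object (`outlier_rate` must be < 0.5).
#' @param protein_archetypes archetype set for protein localization classes;
#'   channel count must equal `config$n_channels`.
#' @return list with `psm_table` (tibble: psm_id, master_protein, peptide_seq,
#'   unique_flag, co_isolation, signal_to_noise, channel_1..N), `psm_truth`
#'   (per-PSM `is_outlier`), `protein_truth` (protein, localization,
#'   `is_contaminant`, `shares_contaminant_peptide`), and `contaminant_ids`
#'   (the cRAP accessions).
#' @export
simulate_psm_table <- function(config, protein_archetypes) {
  assert_that(inherits(config, "gradloc_sim_config"), "config must come from sim_config()")
  assert_that(config$outlier_rate < 0.5, "invalid config: outlier_rate must be < 0.5")
  assert_that(inherits(protein_archetypes, "gradloc_archetypes"),
              "protein_archetypes must come from generate_archetypes()")
  assert_that(protein_archetypes$fraction_count == config$n_channels,
              "archetype fraction count must equal config$n_channels")
  with_seed(config$seed + 1L, simulate_psm_impl(config, protein_archetypes))
}

simulate_psm_impl <- function(config, ark) {
  locs <- ark$localizations
  A <- ark$profiles
  nch <- config$n_channels
  chan_cols <- paste0("channel_", seq_len(nch))

  prot_ids <- sprintf("PR%04d", seq_len(config$n_proteins))
  prot_loc <- sample(locs, config$n_proteins, replace = TRUE)
  prot_ab <- rlnorm(config$n_proteins, log(1e6), 1)
  n_psm <- 1L + rpois(config$n_proteins, config$psms_per_protein - 1)

  crap_ids <- sprintf("cRAP%02d", seq_len(config$n_contaminants))
  crap_npsm <- 1L + rpois(config$n_contaminants, 2)

  rand_pep <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   12, replace = TRUE), collapse = "")
    }, character(1))
  }

  rows <- list()
  add_psms <- function(protein, k, profile, ab, peptides = NULL) {
    if (k == 0) return(NULL)
    pep <- peptides %||% rand_pep(k)
    scale <- rlnorm(k, 0, 0.3) * ab
    noise <- if (config$psm_noise_sd > 0) {
      matrix(rlnorm(k * nch, 0, config$psm_noise_sd), k, nch)
    } else {
      matrix(1, k, nch)
    }
    intens <- (scale %o% profile) * noise
    colnames(intens) <- chan_cols
    tibble::tibble(master_protein = protein, peptide_seq = pep,
                   unique_flag = TRUE,
                   tibble::as_tibble(intens, .name_repair = "minimal"))
  }

  for (i in seq_along(prot_ids)) {
    rows[[length(rows) + 1]] <-
      add_psms(prot_ids[i], n_psm[i], A[prot_loc[i], ], prot_ab[i])
  }
  # cRAP contaminants: diffuse profiles, their own peptides
  crap_peps <- vector("list", config$n_contaminants)
  for (i in seq_along(crap_ids)) {
    prof <- rdirichlet(1, rep(2, nch))[1, ]
    crap_peps[[i]] <- rand_pep(crap_npsm[i])
    rows[[length(rows) + 1]] <-
      add_psms(crap_ids[i], crap_npsm[i], prof, mean(prot_ab),
               peptides = crap_peps[[i]])
  }
  psm <- dplyr::bind_rows(rows)

  # endogenous proteins that share one observed peptide with a cRAP protein
  shared <- character(0)
  if (config$n_shared_peptide_contaminants > 0) {
    shared <- sample(prot_ids, config$n_shared_peptide_contaminants)
    for (i in seq_along(shared)) {
      crap_i <- ((i - 1) %% config$n_contaminants) + 1
      j <- which(psm$master_protein == shared[i])[1]
      psm$peptide_seq[j] <- crap_peps[[crap_i]][1]
    }
  }

  # a sprinkle of non-unique master assignments (excluded by the PSM filter)
  n_nonuniq <- max(0L, round(0.02 * nrow(psm)))
  if (n_nonuniq > 0) {
    psm$unique_flag[sample(nrow(psm), n_nonuniq)] <- FALSE
  }

  # planted outlier PSMs: alien archetype profile, at most one per protein,
  # and only in proteins that keep >= 3 clean unique PSMs after the earlier
  # filters, so the distance rule isolates exactly the planted PSM
  psm$is_outlier <- FALSE
  uniq_counts <- table(psm$master_protein[psm$unique_flag &
                                            psm$master_protein %in% prot_ids])
  eligible <- setdiff(names(which(uniq_counts >= 4)), shared)
  n_out <- min(length(eligible), round(config$outlier_rate * nrow(psm)))
  if (n_out > 0) {
    out_prot <- sample(eligible, n_out)
    for (pr in out_prot) {
      j <- sample(which(psm$master_protein == pr & psm$unique_flag), 1)
      loc_i <- match(prot_loc[match(pr, prot_ids)], locs)
      alien <- locs[(loc_i + floor(length(locs) / 2) - 1) %% length(locs) + 1]
      scale <- sum(psm[j, chan_cols])
      psm[j, chan_cols] <- as.list(A[alien, ] / sum(A[alien, ]) * scale)
      psm$is_outlier[j] <- TRUE
    }
  }

  # MS quality covariates: outliers skew to high co-isolation / low s2n
  psm$co_isolation <- pmin(100, rlnorm(nrow(psm), log(10), 0.6) *
                             ifelse(psm$is_outlier, 3, 1))
  psm$signal_to_noise <- rlnorm(nrow(psm), log(20), 0.5) /
    ifelse(psm$is_outlier, 2, 1)

  # intensity-dependent missingness, calibrated to the configured overall rate
  if (config$missing_rate > 0) {
    m <- as.matrix(psm[, chan_cols])
    z <- scale(log(as.vector(m)))[, 1]
    f <- function(a) mean(plogis(a - config$missing_steepness * z)) -
      config$missing_rate
    a <- stats::uniroot(f, c(-50, 50))$root
    mask <- rbinom(length(z), 1, plogis(a - config$missing_steepness * z)) == 1
    m[matrix(mask, nrow(m))] <- NA_real_
    psm[, chan_cols] <- tibble::as_tibble(m, .name_repair = "minimal")
  }

  psm$psm_id <- sprintf("PSM%05d", seq_len(nrow(psm)))
  psm_table <- psm[, c("psm_id", "master_protein", "peptide_seq",
                       "unique_flag", "co_isolation", "signal_to_noise",
                       chan_cols)]
  psm_truth <- psm[, c("psm_id", "master_protein", "is_outlier")]
  protein_truth <- tibble::tibble(
    protein = c(prot_ids, crap_ids),
    localization = c(prot_loc, rep(NA_character_, length(crap_ids))),
    is_contaminant = c(rep(FALSE, length(prot_ids)),
                       rep(TRUE, length(crap_ids))),
    shares_contaminant_peptide = c(prot_ids %in% shared,
                                   rep(FALSE, length(crap_ids)))
  )
  list(psm_table = psm_table, psm_truth = psm_truth,
       protein_truth = protein_truth, contaminant_ids = crap_ids)
}
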