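#' Simulation configuration
#'
#' Collects every knob of the synthetic fractionation experiment. The defaults
#' mirror the design of the fractionation study the package models: 8 gradient
#' fractions, 3 replicates, two conditions (control and a stress condition in
#' which mRNAs relocalize to granules), spike-ins at ~1% of the library, and
#' negative-binomial counting noise.
#'
#' @param n_transcripts number of endogenous transcripts (markers included).
#' @param n_proteins number of proteins for the PSM-level simulation.
#' @param fraction_count gradient fractions (default 8).
#' @param replicates replicates per condition (default 3).
#' @param conditions condition labels; the second one triggers relocalization.
#' @param localizations localization names; must match the archetype set used.
#' @param dirichlet_concentrations named list (one entry per biotype) of
#'   Dirichlet concentration vectors over `localizations` from which
#'   ground-truth proportion rows are drawn.
#' @param biotype_proportions named probabilities for assigning biotypes to
#'   non-marker transcripts.
#' @param n_markers_per_class pure-localization marker transcripts simulated
#'   per localization class.
#' @param dispersion negative-binomial dispersion of counts (0 = noiseless,
#'   counts equal their expectation exactly).
#' @param library_size expected sequenced counts per fraction library.
#' @param library_size_sd log-normal sd of the per-library depth factor.
#' @param spikein_fraction_of_library spike-in share of a typical library.
#' @param n_spikeins number of spike-in features.
#' @param content per-fraction recovery multiplier (strictly positive,
#'   length `fraction_count` or 1). Uniform by default: the per-fraction RNA
#'   content differences seen by the spike-in adjustment are then purely
#'   emergent from where the transcriptome localizes.
#' @param proportion_used share of each fraction used for library prep.
#' @param relocalization named coefficients `intercept`, `log_length`,
#'   `au_content`, `membrane_prior` of the logistic granule-gain rule applied
#'   to mRNAs in the stress condition.
#' @param abundance_meanlog,abundance_sdlog log-normal transcript abundance.
#' @param n_rbps RNA-binding proteins for the binary binding table.
#' @param rbp_binding_rate Bernoulli rate of RBP-transcript binding.
#' @param psms_per_protein mean number of PSMs per protein beyond the first.
#' @param n_channels TMT channels of the PSM table (defaults to
#'   `fraction_count`).
#' @param psm_noise_sd log-normal sd of PSM reporter intensities.
#' @param n_contaminants cRAP contaminant proteins planted in the PSM table.
#' @param n_shared_peptide_contaminants endogenous-looking proteins sharing a
#'   peptide with a cRAP protein.
#' @param outlier_rate share of PSMs displaced to an alien profile (must be
#'   < 0.5).
#' @param missing_rate overall share of PSM entries masked as missing.
#' @param missing_steepness slope of the logistic intensity-dependent
#'   missingness (left-censoring strength).
#' @param seed integer seed; the same config and seed reproduce every table
#'   bit-identically.
#' @return a `gradloc_sim_config` list.
#' @export
sim_config <- function(n_transcripts = 3000,
                       n_proteins = 300,
                       fraction_count = 8,
                       replicates = 3,
                       conditions = c("control", "upr"),
                       localizations = c("nucleus", "nucleolus", "cytosol",
                                         "cytosol_light", "er", "mitochondria"),
                       dirichlet_concentrations = NULL,
                       biotype_proportions = c(mRNA = 0.8, lncRNA = 0.2),
                       n_markers_per_class = 30,
                       dispersion = 0.02,
                       library_size = 5e6,
                       library_size_sd = 0.05,
                       spikein_fraction_of_library = 0.01,
                       n_spikeins = 20,
                       content = 1,
                       proportion_used = 0.5,
                       relocalization = c(intercept = -5, log_length = 1.2,
                                          au_content = 2, membrane_prior = 1.5),
                       abundance_meanlog = log(50),
                       abundance_sdlog = 1.0,
                       n_rbps = 20,
                       rbp_binding_rate = 0.15,
                       psms_per_protein = 4,
                       n_channels = NULL,
                       psm_noise_sd = 0.1,
                       n_contaminants = 5,
                       n_shared_peptide_contaminants = 3,
                       outlier_rate = 0.05,
                       missing_rate = 0.05,
                       missing_steepness = 1.5,
                       seed = 1L) {
  if (is.null(dirichlet_concentrations)) {
    dirichlet_concentrations <- list(
      mRNA   = c(nucleus = 1.0, nucleolus = 0.1, cytosol = 4.0,
                 cytosol_light = 0.5, er = 1.5, mitochondria = 0.02),
      lncRNA = c(nucleus = 2.5, nucleolus = 0.3, cytosol = 2.5,
                 cytosol_light = 0.2, er = 0.02, mitochondria = 0.02)
    )
    dirichlet_concentrations <- lapply(dirichlet_concentrations, function(a) {
      stats::setNames(a[seq_along(localizations)], localizations)
    })
  }
  content <- rep_len(content, fraction_count)
  proportion_used <- rep_len(proportion_used, fraction_count)

  assert_that(all(content > 0), "invalid config: content vector must be strictly positive")
  assert_that(all(proportion_used > 0 & proportion_used <= 1),
              "invalid config: proportion_used must be in (0, 1]")
  rates <- c(spikein_fraction_of_library, outlier_rate, missing_rate,
             rbp_binding_rate)
  assert_that(all(rates >= 0 & rates <= 1), "invalid config: rates must be in [0, 1]")
  assert_that(outlier_rate < 0.5, "invalid config: outlier_rate must be < 0.5")
  assert_that(dispersion >= 0, "invalid config: dispersion must be >= 0")
  assert_that(length(conditions) >= 1, "invalid config: need >= 1 condition")
  assert_that(abs(sum(biotype_proportions) - 1) < 1e-9,
              "invalid config: biotype_proportions must sum to 1")
  for (bt in names(biotype_proportions)) {
    a <- dirichlet_concentrations[[bt]]
    assert_that(!is.null(a) && length(a) == length(localizations),
                sprintf("invalid config: dirichlet_concentrations lacks biotype '%s'", bt))
  }

  structure(list(
    n_transcripts = n_transcripts, n_proteins = n_proteins,
    fraction_count = as.integer(fraction_count),
    replicates = as.integer(replicates), conditions = conditions,
    localizations = localizations,
    dirichlet_concentrations = dirichlet_concentrations,
    biotype_proportions = biotype_proportions,
    n_markers_per_class = n_markers_per_class,
    dispersion = dispersion, library_size = library_size,
    library_size_sd = library_size_sd,
    spikein_fraction_of_library = spikein_fraction_of_library,
    n_spikeins = n_spikeins, content = content,
    proportion_used = proportion_used, relocalization = relocalization,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    n_rbps = n_rbps, rbp_binding_rate = rbp_binding_rate,
    psms_per_protein = psms_per_protein,
    n_channels = as.integer(n_channels %||% fraction_count),
    psm_noise_sd = psm_noise_sd, n_contaminants = n_contaminants,
    n_shared_peptide_contaminants = n_shared_peptide_contaminants,
    outlier_rate = outlier_rate, missing_rate = missing_rate,
    missing_steepness = missing_steepness,
    seed = as.integer(seed)
  ), class = "gradloc_sim_config")
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(g)
  zero <- sw == 0
  if (any(zero)) {            # all-tiny alphas can underflow; fall back to argmax
    g[zero, ] <- t(vapply(which(zero), function(i) {
      v <- numeric(k); v[which.max(alpha)] <- 1; v
    }, numeric(k)))
    sw <- rowSums(g)
  }
  sweep(g, 1, sw, "/")
}
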