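#' Run the full proportion-recovery pipeline on a dataset
#'
#' Convenience chain for a simulated (or identically structured real)
#' experiment: estimate per-fraction RNA content from the spike-ins,
#' content-adjust and row-normalize the profiles, build the marker basis per
#' condition, deconvolve every feature x replicate profile, and average the
#' QC-passing replicates.
#'
#' @param dataset a `gradloc_dataset` from [simulate_rna_experiment()], or a
#'   list with `rna_profiles`, `spikeins` and `markers` of the same shape.
#' @param mode basis mode, see [build_marker_basis()]. The default
#'   "sedimentation" keeps every marker class as its own basis row.
#' @param min_replicates replicate minimum for [average_replicates()].
#' @param r2_min,intercept_max QC thresholds for [estimate_proportions()].
#' @return list: `proportions` (averaged table), `estimates` (per-replicate
#'   fits), `normalized` (row-normalized profiles), `content`, `bases`
#'   (per-condition marker bases).
#' @export
recover_proportions <- function(dataset, mode = "sedimentation",
                                min_replicates = 2, r2_min = 0.90,
                                intercept_max = 0.05) {
  content <- estimate_content_by_library(dataset$rna_profiles,
                                         dataset$spikeins)
  normalized <- normalize_profiles(dataset$rna_profiles, content)
  conditions <- unique(normalized$condition)
  estimates <- dplyr::bind_rows(lapply(conditions, function(cond) {
    basis <- build_marker_basis(normalized, dataset$markers, mode = mode,
                                condition = cond)
    sub <- normalized[normalized$condition == cond, , drop = FALSE]
    deconvolve_profiles(restamp_profiles(sub, normalized), basis,
                        r2_min = r2_min, intercept_max = intercept_max)
  }))
  bases <- lapply(stats::setNames(conditions, conditions), function(cond) {
    build_marker_basis(normalized, dataset$markers, mode = mode,
                       condition = cond)
  })
  proportions <- average_replicates(estimates, min_replicates = min_replicates)
  list(proportions = proportions, estimates = estimates,
       normalized = normalized, content = content, bases = bases)
}
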