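# PSM-level processing of multiplexed (TMT) proteomics quantifications.

channel_cols <- function(x) grep("^channel_[0-9]+$", names(x), value = TRUE)

channel_matrix <- function(x) {
  m <- as.matrix(x[, channel_cols(x), drop = FALSE])
  rownames(m) <- x$psm_id
  storage.mode(m) <- "double"
  m
}

#' Remove contaminant proteins and their peptide-sharing partners
#'
#' Drops all PSMs of the listed contaminant (cRAP) proteins, and — because a
#' shared peptide makes a protein's quantification unattributable — also all
#' PSMs of any master protein that shares at least one observed peptide
#' sequence with a contaminant protein.
#'
#' @param psms PSM tibble (`psm_id`, `master_protein`, `peptide_seq`,
#'   channel columns, ...).
#' @param contaminant_ids contaminant protein accessions.
#' @return filtered PSM tibble; attribute `removal_report` counts removals by
#'   reason and `flagged_proteins` lists the peptide-sharing proteins.
#' @export
remove_contaminants <- function(psms, contaminant_ids) {
  is_crap <- psms$master_protein %in% contaminant_ids
  crap_peps <- unique(psms$peptide_seq[is_crap])
  shares <- psms$peptide_seq %in% crap_peps & !is_crap
  flagged <- unique(psms$master_protein[shares])
  drop <- is_crap | psms$master_protein %in% flagged
  out <- psms[!drop, , drop = FALSE]
  attr(out, "removal_report") <- tibble::tibble(
    reason = c("contaminant", "shares_contaminant_peptide"),
    n_psms = c(sum(is_crap), sum(drop & !is_crap))
  )
  attr(out, "flagged_proteins") <- flagged
  out
}

#' Filter PSMs on master-protein uniqueness and missingness
#'
#' Removes PSMs without a unique master protein and PSMs with more than
#' `max_missing_share` missing reporter values (strictly more: 20% missing of
#' 10 channels is retained).
#'
#' @param psms PSM tibble.
#' @param max_missing_share maximum tolerated missing share (default 0.2).
#' @return filtered PSM tibble.
#' @export
filter_psms <- function(psms, max_missing_share = 0.2) {
  m <- channel_matrix(psms)
  missing_share <- rowMeans(is.na(m))
  keep <- psms$unique_flag & missing_share <= max_missing_share
  psms[keep, , drop = FALSE]
}

#' Impute missing reporter intensities by profile-space knn
#'
#' Each PSM row is first scaled to sum 1 over its observed channels, so that
#' nearest neighbors share similar abundance *profiles* over the fractions
#' rather than similar average abundance. Missing entries are set to the mean
#' of the k nearest rows (Euclidean distance on the channels observed in both
#' rows, rescaled by the shared-channel count), and rows are rescaled back to
#' their original observed totals, restoring observed entries exactly.
#'
#' @param psms PSM tibble with at most the filtered missingness per row.
#' @param k neighbors (default 10). With fewer than k complete candidate
#'   rows, all available are used with a warning.
#' @return PSM tibble without missing values.
#' @export
impute_knn <- function(psms, k = 10) {
  m <- channel_matrix(psms)
  if (!anyNA(m)) return(psms)
  obs_tot <- rowSums(m, na.rm = TRUE)
  norm <- m / obs_tot
  incomplete <- which(rowSums(is.na(norm)) > 0)
  complete_rows <- which(rowSums(is.na(norm)) == 0)
  if (length(complete_rows) < k) {
    rlang::warn(sprintf("only %d complete rows available for knn (k = %d)",
                        length(complete_rows), k))
  }
  filled <- norm
  for (i in incomplete) {
    cand <- complete_rows
    shared <- !is.na(norm[i, ])
    # mean squared difference on shared observed channels
    d2 <- colMeans((t(norm[cand, shared, drop = FALSE]) - norm[i, shared])^2)
    nn <- cand[order(d2)[seq_len(min(k, length(cand)))]]
    miss <- is.na(norm[i, ])
    filled[i, miss] <- colMeans(norm[nn, miss, drop = FALSE])
  }
  out <- psms
  out[, channel_cols(psms)] <- tibble::as_tibble(filled * obs_tot,
                                                 .name_repair = "minimal")
  out
}

#' Remove outlier PSMs by median profile distance
#'
#' For each PSM, the median Euclidean distance between its row-normalized
#' profile and the profiles of all sibling PSMs of the same master protein;
#' PSMs with a median distance over `distance_threshold` are removed. The
#' rule is applied literally, so two mutually distant PSMs of a 2-PSM protein
#' are both removed (the protein then fails the downstream >= 2 PSM rule).
#'
#' @param psms imputed PSM tibble (no missing values).
#' @param distance_threshold removal threshold (default 0.2).
#' @return filtered PSM tibble; attribute `outlier_psms` lists removals.
#' @export
remove_outlier_psms <- function(psms, distance_threshold = 0.2) {
  m <- channel_matrix(psms)
  assert_that(!anyNA(m), "remove_outlier_psms requires imputed profiles")
  prof <- m / rowSums(m)
  drop <- logical(nrow(psms))
  for (ids in split(seq_len(nrow(psms)), psms$master_protein)) {
    if (length(ids) < 2) next
    d <- as.matrix(dist(prof[ids, , drop = FALSE]))
    med <- vapply(seq_along(ids), function(j) median(d[j, -j]), numeric(1))
    drop[ids[med > distance_threshold]] <- TRUE
  }
  out <- psms[!drop, , drop = FALSE]
  attr(out, "outlier_psms") <- psms$psm_id[drop]
  out
}

#' Median-center reporter channels
#'
#' Divides each channel by its median over PSMs and rescales by the grand
#' median, so every channel median is equal afterwards (divisive centering;
#' profiles are row-normalized later, making this equivalent to aligning
#' channel scales).
#'
#' @param psms PSM tibble without missing values.
#' @return median-centered PSM tibble.
#' @export
median_center <- function(psms) {
  m <- channel_matrix(psms)
  assert_that(!anyNA(m), "median_center requires imputed profiles")
  med <- apply(m, 2, median)
  assert_that(all(med > 0), "zero channel median")
  m <- sweep(m, 2, med, "/") * exp(mean(log(med)))
  out <- psms
  out[, channel_cols(psms)] <- tibble::as_tibble(m, .name_repair = "minimal")
  out
}

#' Aggregate PSMs to normalized protein profiles
#'
#' Sums PSM-level abundances per protein, keeps proteins with at least two
#' PSMs, and row-sum normalizes so each protein's abundance across the
#' fractions of a replicate equals one.
#'
#' @param psms processed PSM tibble.
#' @param replicate replicate label stored with the output (one PSM table =
#'   one multiplexed run = one replicate).
#' @return tibble: protein, replicate, psm_count, channel columns (row sums
#'   1).
#' @export
aggregate_proteins <- function(psms, replicate = 1L) {
  cc <- channel_cols(psms)
  agg <- psms |>
    dplyr::group_by(protein = .data$master_protein) |>
    dplyr::summarise(psm_count = dplyr::n(),
                     dplyr::across(dplyr::all_of(cc), sum), .groups = "drop") |>
    dplyr::filter(.data$psm_count >= 2)
  if (nrow(agg) == 0) rlang::warn("no proteins with >= 2 PSMs")
  m <- as.matrix(agg[, cc])
  agg[, cc] <- tibble::as_tibble(m / rowSums(m), .name_repair = "minimal")
  tibble::tibble(protein = agg$protein, replicate = replicate,
                 psm_count = agg$psm_count, agg[, cc])
}

#' Full PSM-to-protein processing pipeline
#'
#' Chains [remove_contaminants()], [filter_psms()], [impute_knn()],
#' [remove_outlier_psms()], [median_center()] and [aggregate_proteins()] with
#' the default thresholds.
#'
#' @param psms raw PSM tibble.
#' @param contaminant_ids contaminant accessions.
#' @inheritParams aggregate_proteins
#' @inheritParams impute_knn
#' @inheritParams remove_outlier_psms
#' @return list: `proteins` (protein profile tibble), `removed_contaminants`
#'   (report from [remove_contaminants()]), `outlier_psms`.
#' @export
process_psm_table <- function(psms, contaminant_ids, replicate = 1L,
                              k = 10, distance_threshold = 0.2) {
  step1 <- remove_contaminants(psms, contaminant_ids)
  report <- attr(step1, "removal_report")
  flagged <- attr(step1, "flagged_proteins")
  step2 <- filter_psms(step1)
  step3 <- impute_knn(step2, k = k)
  step4 <- remove_outlier_psms(step3, distance_threshold = distance_threshold)
  outliers <- attr(step4, "outlier_psms")
  step5 <- median_center(step4)
  list(proteins = aggregate_proteins(step5, replicate = replicate),
       removed_contaminants = report, flagged_proteins = flagged,
       outlier_psms = outliers)
}
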