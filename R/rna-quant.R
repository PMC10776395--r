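#' Iodixanol concentration from a refractometer reading
#'
#' Converts the refractometer scale reading of a gradient fraction to the
#' iodixanol concentration (% w/v) with the instrument calibration
#' `iodixanol% = RI / 0.83 - 10.111`. Note the calibration is for the
#' refractometer's scale reading, not the physical refractive index of the
#' solution (values near 1.34 would map to negative concentrations).
#'
#' @param ri refractometer reading(s), finite and > 0.
#' @return iodixanol percentage(s) (w/v).
#' @examples
#' iodixanol_from_refractive_index(8.39213)  # ~0 %
#' @export
iodixanol_from_refractive_index <- function(ri) {
  assert_that(is.numeric(ri) && all(is.finite(ri)) && all(ri > 0),
              "refractometer reading must be finite and > 0")
  ri / 0.83 - 10.111
}

#' Estimate per-fraction RNA content from spike-ins
#'
#' Spike-in features are added to each fraction library at a fixed absolute
#' amount, so the ratio of endogenous to spike-in signal, corrected by the
#' proportion of the fraction used for library preparation, is proportional to
#' the fraction's total RNA content:
#' `content_f ~ (endogenous_f / spikein_f) / proportion_used_f`, returned
#' normalized to sum 1.
#'
#' @param table a raw-state [profile_table()] (endogenous features) for a
#'   single library set (one condition x replicate), or anything with fraction
#'   columns; endogenous totals are its fraction column sums.
#' @param spikeins list or data frame with `spikein_total` (per-fraction
#'   spike-in abundance totals, same scale as the table) and
#'   `proportion_used`.
#' @return numeric content vector (length = fractions, sums to 1).
#' @export
estimate_fraction_content <- function(table, spikeins) {
  endo <- colSums(fraction_matrix(table))
  spike <- spikeins$spikein_total
  used <- spikeins$proportion_used %||% rep(1, length(endo))
  assert_that(length(spike) == length(endo),
              "spike-in totals must have one value per fraction")
  bad <- which(!(spike > 0))
  if (length(bad) > 0) {
    rlang::abort(sprintf("zero spike-in signal in fraction(s): %s",
                         paste(bad, collapse = ", ")))
  }
  content <- (endo / spike) / used
  content / sum(content)
}

#' Estimate fraction content for every library of an experiment
#'
#' Applies [estimate_fraction_content()] per condition x replicate.
#'
#' @param profiles raw-state [profile_table()].
#' @param spikeins long tibble with columns `condition`, `replicate`,
#'   `fraction`, `spikein_total`, `proportion_used` (as produced by
#'   [simulate_rna_experiment()]).
#' @return tibble `condition`, `replicate`, `fraction`, `content`.
#' @export
estimate_content_by_library <- function(profiles, spikeins) {
  keys <- dplyr::distinct(profiles[, c("condition", "replicate")])
  purrr::pmap_dfr(keys, function(condition, replicate) {
    tab <- profiles[profiles$condition == condition &
                      profiles$replicate == replicate, , drop = FALSE]
    sp <- spikeins[spikeins$condition == condition &
                     spikeins$replicate == replicate, , drop = FALSE]
    sp <- sp[order(sp$fraction), , drop = FALSE]
    tibble::tibble(condition = condition, replicate = replicate,
                   fraction = seq_len(n_fractions(tab)),
                   content = estimate_fraction_content(tab, sp))
  })
}

#' Content-adjust and row-normalize fraction profiles
#'
#' Multiplies each abundance by its fraction's RNA content and then divides
#' each feature x replicate row by its sum, yielding the share of a feature's
#' molecules in each fraction. All-zero rows are dropped (count reported via
#' a message).
#'
#' @param table raw-state [profile_table()].
#' @param content either a numeric vector (one value per fraction, applied to
#'   every library) or the per-library tibble from
#'   [estimate_content_by_library()].
#' @return a row-normalized [profile_table()].
#' @export
normalize_profiles <- function(table, content) {
  assert_that(profile_state(table) %in% c("raw", "row_normalized"),
              "normalize_profiles expects a raw or row_normalized table")
  fc <- fraction_cols(table)
  m <- as.matrix(table[, fc])
  if (is.data.frame(content)) {
    assert_that(all(content$content >= 0), "negative content")
    key <- paste(table$condition, table$replicate)
    for (k in unique(key)) {
      rows <- key == k
      ck <- content[paste(content$condition, content$replicate) == k, ]
      ck <- ck[order(ck$fraction), ]
      assert_that(nrow(ck) == length(fc),
                  sprintf("content missing for library %s", k))
      m[rows, ] <- sweep(m[rows, , drop = FALSE], 2, ck$content, "*")
    }
  } else {
    assert_that(is.numeric(content) && length(content) == length(fc),
                "content must have one value per fraction")
    assert_that(all(content >= 0), "negative content")
    m <- sweep(m, 2, content, "*")
  }
  s <- rowSums(m)
  keep <- s > 0
  if (any(!keep)) {
    rlang::inform(sprintf("dropped %d all-zero rows during normalization",
                          sum(!keep)))
  }
  out <- table[keep, , drop = FALSE]
  out[, fc] <- tibble::as_tibble(m[keep, , drop = FALSE] / s[keep],
                                 .name_repair = "minimal")
  profile_table(out, level = profile_level(table), state = "row_normalized")
}

#' Expression filter for fraction profiles
#'
#' Removes features that are too lowly or too sparsely expressed within a
#' condition: mean abundance below `min_mean` (0.5 TPM default, per the
#' density design; use 1 CPM for sedimentation data) or zero abundance in at
#' least `max_zero_share` of the samples (2/3 default; 0.2 for sedimentation,
#' where the rule is "more than", see `zero_share_strict`). A "sample" is one
#' replicate library of the gradient: the per-replicate abundance is the mean
#' across that replicate's fractions.
#'
#' @param table raw-state [profile_table()].
#' @param condition condition whose samples drive the filter.
#' @param min_mean minimum mean abundance over the condition's samples.
#' @param max_zero_share share of zero samples at/over which a feature is
#'   dropped.
#' @param zero_share_strict if TRUE the zero rule fires only when the share
#'   strictly exceeds `max_zero_share` (the sedimentation variant); default
#'   FALSE fires at `>=` (the density variant).
#' @return filtered table; attribute `filter_report` counts removals per rule.
#' @export
filter_low_abundance <- function(table, condition,
                                 min_mean = 0.5,
                                 max_zero_share = 2 / 3,
                                 zero_share_strict = FALSE) {
  assert_that(condition %in% table$condition,
              sprintf("condition '%s' not present", condition))
  fc <- fraction_cols(table)
  cond_tab <- table[table$condition == condition, , drop = FALSE]
  per_sample <- cond_tab |>
    dplyr::mutate(.abund = rowMeans(dplyr::pick(dplyr::all_of(fc)))) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(mean_abund = mean(.data$.abund),
                     zero_share = mean(.data$.abund == 0), .groups = "drop")
  low <- per_sample$feature_id[per_sample$mean_abund < min_mean]
  zero <- if (zero_share_strict) {
    per_sample$feature_id[per_sample$zero_share > max_zero_share]
  } else {
    per_sample$feature_id[per_sample$zero_share >= max_zero_share]
  }
  drop <- union(low, zero)
  out <- table[!table$feature_id %in% drop, , drop = FALSE]
  if (nrow(out) == 0) rlang::warn("expression filter removed every feature")
  out <- profile_table(out, profile_level(table), profile_state(table))
  attr(out, "filter_report") <- tibble::tibble(
    rule = c("mean_below_threshold", "zero_share", "total_removed"),
    n = c(length(low), length(zero), length(drop))
  )
  out
}

#' Exclude lncRNAs with close protein-coding neighbors
#'
#' Sequencing reads frequently bridge a lncRNA and an adjacent protein-coding
#' gene, corrupting the lncRNA's profile. lncRNAs with a protein-coding gene
#' whose nearest edge lies within 15 kb downstream or 30 kb upstream
#' (orientation taken from the lncRNA's strand; overlap counts as distance 0)
#' are removed. Other biotypes are untouched.
#'
#' @param feature_list character vector of gene ids to filter.
#' @param gene_annotation data frame (or GRanges, with `gene_id`/`biotype`
#'   metadata columns) with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`; lncRNAs are `biotype == "lncRNA"`, protein-coding
#'   genes `"protein_coding"`.
#' @param downstream_window,upstream_window exclusion windows in bp.
#' @return filtered feature list.
#' @export
exclude_neighbor_lncrnas <- function(feature_list, gene_annotation,
                                     downstream_window = 15000,
                                     upstream_window = 30000) {
  ann <- as_annotation_df(gene_annotation)
  assert_that(all(c("gene_id", "chrom", "start", "end", "strand", "biotype")
                  %in% names(ann)), "annotation lacks required columns")
  assert_that(all(ann$strand %in% c("+", "-")),
              "missing or invalid strand in annotation")
  lnc <- ann[ann$biotype == "lncRNA" & ann$gene_id %in% feature_list, ,
             drop = FALSE]
  pc <- ann[ann$biotype == "protein_coding", , drop = FALSE]
  if (nrow(lnc) == 0 || nrow(pc) == 0) return(feature_list)

  excluded <- vapply(seq_len(nrow(lnc)), function(i) {
    g <- lnc[i, ]
    near <- pc[pc$chrom == g$chrom, , drop = FALSE]
    if (nrow(near) == 0) return(FALSE)
    # gap between nearest edges, 0 when overlapping
    gap_right <- pmax(0, near$start - g$end - 1)   # neighbor right of lncRNA
    gap_left <- pmax(0, g$start - near$end - 1)    # neighbor left of lncRNA
    overlap <- near$start <= g$end & near$end >= g$start
    if (g$strand == "+") {
      down <- ifelse(near$start > g$end, gap_right, Inf)
      up <- ifelse(near$end < g$start, gap_left, Inf)
    } else {
      down <- ifelse(near$end < g$start, gap_left, Inf)
      up <- ifelse(near$start > g$end, gap_right, Inf)
    }
    any(overlap) || any(down <= downstream_window) ||
      any(up <= upstream_window)
  }, logical(1))

  setdiff(feature_list, lnc$gene_id[excluded])
}

as_annotation_df <- function(x) {
  if (inherits(x, "GRanges")) {
    df <- as.data.frame(x)
    names(df)[names(df) == "seqnames"] <- "chrom"
    return(df)
  }
  as.data.frame(x)
}
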