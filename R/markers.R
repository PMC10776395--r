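#' Marker-set container
#'
#' A marker set maps localizations to member ids (genes or transcripts), with
#' a provenance tag per member (`apriori`, `nnmf` or `curated`). A member may
#' belong to exactly one localization.
#'
#' @param member_id character ids.
#' @param localization character localization per member.
#' @param provenance provenance tag(s).
#' @param level "gene" or "transcript".
#' @return a `gradloc_markers` tibble.
#' @export
marker_set <- function(member_id, localization, provenance = "apriori",
                       level = c("gene", "transcript")) {
  level <- match.arg(level)
  x <- tibble::tibble(member_id = member_id, localization = localization,
                      provenance = rep_len(provenance, length(member_id)))
  dup <- x$member_id[duplicated(x$member_id)]
  conflicted <- unique(x$member_id[x$member_id %in% dup])
  if (length(conflicted) > 0) {
    multi <- x |>
      dplyr::distinct(.data$member_id, .data$localization) |>
      dplyr::count(.data$member_id) |>
      dplyr::filter(.data$n > 1)
    assert_that(nrow(multi) == 0,
                paste0("members assigned to multiple localizations: ",
                       paste(head(multi$member_id, 5), collapse = ", ")))
    x <- dplyr::distinct(x, .data$member_id, .keep_all = TRUE)
  }
  structure(x, class = c("gradloc_markers", class(x)), level = level)
}

#' Define a priori localization markers from enrichment evidence
#'
#' Applies the rule set that anchors each localization before semi-supervised
#' expansion:
#' \itemize{
#'   \item nucleus: > 16-fold enriched in nuclear/cytoplasm fractionation
#'     RNA-seq, or on the manual nuclear lncRNA list;
#'   \item cytosol: significantly enriched in NES-targeted proximity labeling
#'     (APEX), or on the manual cytosolic lncRNA list;
#'   \item er: ER ribosome-profiling enrichment > 2^0.5 AND significant
#'     > 8-fold enrichment in ER(KDEL)-targeted APEX AND a predicted signal
#'     peptide or transmembrane domain;
#'   \item mitochondria: mitochondrially encoded mRNAs.
#' }
#'
#' @param inputs list with (any of) `nuclear_ratio` (tibble gene_id, ratio —
#'   linear nuclear/cytoplasm fold), `nes_apex` (gene_id, enriched logical),
#'   `er_riboseq` (gene_id, enrichment), `kdel_apex` (gene_id, fold,
#'   significant), `sp_tm` (gene_id, has_sp_tm), `mito_genes` (character),
#'   `manual_nuclear`, `manual_cytosol` (character).
#' @param universe quantified gene ids; members not resolvable against it are
#'   dropped (count reported via a message). NULL keeps everything.
#' @param localizations localizations to define.
#' @return gene-level [marker_set()].
#' @export
define_apriori_markers <- function(inputs, universe = NULL,
                                   localizations = c("nucleus", "cytosol",
                                                     "er", "mitochondria")) {
  sets <- list()
  if ("nucleus" %in% localizations) {
    nuc <- character(0)
    if (!is.null(inputs$nuclear_ratio)) {
      nr <- inputs$nuclear_ratio
      assert_that(all(is.finite(nr$ratio)), "non-finite nuclear/cytoplasm ratios")
      nuc <- nr$gene_id[nr$ratio > 16]
    }
    sets$nucleus <- union(nuc, inputs$manual_nuclear %||% character(0))
  }
  if ("cytosol" %in% localizations) {
    cyt <- character(0)
    if (!is.null(inputs$nes_apex)) {
      cyt <- inputs$nes_apex$gene_id[inputs$nes_apex$enriched]
    }
    sets$cytosol <- union(cyt, inputs$manual_cytosol %||% character(0))
  }
  if ("er" %in% localizations) {
    assert_that(!is.null(inputs$er_riboseq) && !is.null(inputs$kdel_apex) &&
                  !is.null(inputs$sp_tm),
                "er markers need er_riboseq, kdel_apex and sp_tm inputs")
    ribo <- inputs$er_riboseq$gene_id[inputs$er_riboseq$enrichment > 2^0.5]
    kdel <- inputs$kdel_apex$gene_id[inputs$kdel_apex$significant &
                                       inputs$kdel_apex$fold > 8]
    sptm <- inputs$sp_tm$gene_id[inputs$sp_tm$has_sp_tm]
    sets$er <- Reduce(intersect, list(ribo, kdel, sptm))
  }
  if ("mitochondria" %in% localizations) {
    sets$mitochondria <- inputs$mito_genes %||% character(0)
  }
  if (!is.null(universe)) {
    n_before <- sum(lengths(sets))
    sets <- lapply(sets, intersect, y = universe)
    dropped <- n_before - sum(lengths(sets))
    if (dropped > 0) {
      rlang::inform(sprintf("%d a priori members failed id resolution", dropped))
    }
  }
  empty <- names(sets)[lengths(sets) == 0]
  assert_that(length(empty) == 0,
              paste0("no markers found for localization(s): ",
                     paste(empty, collapse = ", ")))
  marker_set(unlist(sets, use.names = FALSE),
             rep(names(sets), lengths(sets)), provenance = "apriori")
}

#' Expand a priori markers to full NNMF clusters
#'
#' Associates every a priori localization with the NNMF cluster it overlaps
#' most, and retains the entire cluster as that localization's marker set.
#' Clusters claimed by no localization are reported as novel profiles.
#'
#' @param model a `gradloc_nnmf` fit (with per-feature cluster assignment).
#' @param apriori a gene-level [marker_set()].
#' @return list with `markers` (expanded [marker_set()], provenance `nnmf`;
#'   a priori members keep `apriori`) and `novel_clusters` (named list of
#'   member ids for unclaimed clusters).
#' @export
map_clusters_to_apriori <- function(model, apriori) {
  cl <- model$cluster
  locs <- unique(apriori$localization)
  chosen <- integer(0)
  for (loc in locs) {
    members <- intersect(apriori$member_id[apriori$localization == loc],
                         names(cl))
    assert_that(length(members) > 0,
                sprintf("no a priori members of '%s' present in the matrix", loc))
    counts <- table(cl[members])
    top <- max(counts)
    winners <- names(counts)[counts == top]
    assert_that(length(winners) == 1,
                sprintf("overlap tie for localization '%s' (clusters %s): requires curation",
                        loc, paste(winners, collapse = ", ")))
    chosen[loc] <- as.integer(winners)
  }
  if (anyDuplicated(chosen)) {
    dup <- chosen[duplicated(chosen)][1]
    clash <- names(chosen)[chosen == dup]
    rlang::abort(sprintf("localizations %s map to the same cluster %d",
                         paste(clash, collapse = " and "), dup))
  }
  expanded <- lapply(chosen, function(k) names(cl)[cl == k])
  member_id <- unlist(expanded, use.names = FALSE)
  localization <- rep(names(expanded), lengths(expanded))
  provenance <- ifelse(member_id %in% apriori$member_id, "apriori", "nnmf")
  novel_ids <- setdiff(unique(cl), chosen)
  novel <- lapply(stats::setNames(novel_ids, paste0("cluster_", novel_ids)),
                  function(k) names(cl)[cl == k])
  list(markers = marker_set(member_id, localization, provenance),
       novel_clusters = novel)
}

#' Cytosol-light gene set from condition-shared novel clusters
#'
#' The genes assigned to the novel (a-priori-free) NNMF cluster in both the
#' basal and the stress condition define the cytosol-light (granule) profile.
#'
#' @param novel_basal,novel_stress gene id vectors.
#' @return their intersection (empty with a warning if disjoint).
#' @export
define_cytosol_light <- function(novel_basal, novel_stress) {
  out <- intersect(novel_basal, novel_stress)
  if (length(out) == 0) {
    rlang::warn("no genes shared between the novel clusters; empty cytosol-light set")
  }
  out
}

#' Nucleolus markers from the nuclear cluster and abundant snoRNAs
#'
#' @param nuclear_cluster_genes members of the nucleus-associated NNMF
#'   cluster.
#' @param snorna_ranking snoRNA gene ids ranked by total-RNA abundance
#'   (most abundant first).
#' @param top_n how many top snoRNAs to intersect with (default 30).
#' @return gene id vector.
#' @export
define_nucleolus_markers <- function(nuclear_cluster_genes, snorna_ranking,
                                     top_n = 30) {
  intersect(nuclear_cluster_genes, head(snorna_ranking, top_n))
}

#' Extend gene-level markers to transcript level
#'
#' Takes all transcript isoforms of each gene-level marker whose transcript
#' biotype matches the gene biotype, then removes blacklisted (curated-out)
#' members.
#'
#' @param gene_markers gene-level [marker_set()].
#' @param annotation tibble with `transcript_id`, `gene_id`,
#'   `transcript_biotype`, `gene_biotype`.
#' @param blacklist transcript ids to remove (manual curation).
#' @return transcript-level [marker_set()].
#' @export
extend_to_transcripts <- function(gene_markers, annotation,
                                  blacklist = character(0)) {
  missing_genes <- setdiff(gene_markers$member_id, annotation$gene_id)
  if (length(missing_genes) > 0) {
    rlang::inform(sprintf("%d marker genes absent from annotation, skipped",
                          length(missing_genes)))
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(gene_markers),
    annotation[annotation$transcript_biotype == annotation$gene_biotype, ],
    by = c(member_id = "gene_id"), relationship = "many-to-many"
  )
  n_black <- sum(joined$transcript_id %in% blacklist)
  if (n_black > 0) {
    rlang::inform(sprintf("%d blacklisted transcripts removed", n_black))
  }
  joined <- joined[!joined$transcript_id %in% blacklist, , drop = FALSE]
  marker_set(joined$transcript_id, joined$localization,
             provenance = joined$provenance, level = "transcript")
}

#' Human mitochondrially encoded mRNA markers
#'
#' The mitochondrial genome encodes exactly 13 mRNAs; because mitochondrial
#' transcripts have no cytosolic copies, their mean profile anchors 100%
#' membrane localization in the deconvolution.
#'
#' @return tibble with `gene_id` (Ensembl), `symbol`, `biotype` — 13 rows.
#' @export
mito_mrna_markers <- function() {
  path <- system.file("extdata", "mito_mrna_markers.tsv", package = "gradloc")
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Read / write marker sets as TSV
#'
#' Two-column-plus-provenance TSV (`member_id`, `localization`,
#' `provenance`).
#'
#' @param x a [marker_set()].
#' @param path file path.
#' @param level level flag for reading.
#' @export
write_marker_set <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_set
#' @export
read_marker_set <- function(path, level = "gene") {
  x <- read.delim(path, stringsAsFactors = FALSE)
  marker_set(x$member_id, x$localization,
             provenance = x$provenance %||% "curated", level = level)
}
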