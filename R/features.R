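# Transcript sequence/annotation feature construction for the
# relocalization and localization models.

#' k-mer frequencies of an RNA sequence
#'
#' Counts all overlapping k-mers and divides by the number of windows
#' (`length - k + 1`). The full 4^k vector is returned (RNA alphabet,
#' A/C/G/U) so feature matrices are column-aligned across transcripts.
#'
#' @param sequence character RNA (or DNA) sequence; `T` is treated as `U`.
#' @param k word size (>= 1).
#' @return named frequency vector of length 4^k, summing to 1 when the
#'   sequence has at least one window (all-zero with a warning otherwise).
#' @examples
#' kmer_frequencies("AUAU", 2)[c("AU", "UA")]
#' @export
kmer_frequencies <- function(sequence, k) {
  assert_that(is.character(sequence) && length(sequence) == 1,
              "sequence must be a single string")
  assert_that(k >= 1, "k must be >= 1")
  up <- toupper(sequence)
  assert_that(grepl("^[ACGUT]*$", up), "invalid characters in sequence")
  dna <- chartr("U", "T", up)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(dna),
                                                 width = k)
  names(counts) <- chartr("T", "U", names(counts))
  n_windows <- nchar(up) - k + 1
  if (n_windows < 1) {
    rlang::warn("sequence shorter than k; returning zero frequencies")
    return(counts * 0)
  }
  counts / n_windows
}

kmer_frequency_matrix <- function(sequences, k) {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", toupper(sequences)))
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
  colnames(counts) <- chartr("T", "U", colnames(counts))
  windows <- pmax(1, Biostrings::width(dna) - k + 1)
  counts / windows
}

#' Binary cytosolic labels from cytosol proportions
#'
#' `1` for proportions of at least 2/3 (cytosolic), `0` below 1/3
#' (not cytosolic); proportions in between get `NA` and are excluded from
#' the modeling set.
#'
#' @param proportions cytosol proportions in `[0, 1]`.
#' @return integer labels with NA for the excluded mid-band.
#' @export
binarize_cytosol <- function(proportions) {
  assert_that(all(proportions >= 0 & proportions <= 1),
              "proportions must lie in [0, 1]")
  ifelse(proportions >= 2 / 3, 1L, ifelse(proportions < 1 / 3, 0L, NA_integer_))
}

#' Select RBP binding columns by target count
#'
#' Keeps RNA-binding proteins whose bound targets within the analysis
#' universe number strictly more than `min_targets`, and returns their
#' binding as binary 0/1 columns over the universe.
#'
#' @param binding_table long tibble `rbp`, `feature_id`.
#' @param min_targets strict lower bound on targets within the universe.
#' @param universe feature ids defining rows of the output.
#' @return tibble `feature_id` + one 0/1 column per retained RBP.
#' @export
select_rbp_columns <- function(binding_table, min_targets, universe) {
  bt <- binding_table[binding_table$feature_id %in% universe, , drop = FALSE]
  counts <- table(bt$rbp)
  keep <- names(counts)[counts > min_targets]
  out <- tibble::tibble(feature_id = universe)
  if (length(keep) == 0) {
    rlang::warn("no RBPs exceed the target-count threshold")
    return(out)
  }
  for (r in keep) {
    out[[r]] <- as.integer(universe %in% bt$feature_id[bt$rbp == r])
  }
  out
}

#' Ribosome density of a coding sequence
#'
#' Footprint counts over the coding sequence divided by its length.
#'
#' @param cds_counts RNase-protected footprint counts on the CDS (>= 0).
#' @param cds_length CDS length in nucleotides (> 0).
#' @return densities (counts per nucleotide).
#' @export
ribosome_density <- function(cds_counts, cds_length) {
  assert_that(all(cds_counts >= 0), "counts must be >= 0")
  assert_that(all(cds_length > 0), "CDS length must be > 0")
  cds_counts / cds_length
}

#' Count upstream AUGs by reading frame
#'
#' AUGs wholly within the 5' UTR, split by frame relative to the annotated
#' CDS start: an AUG at position p is in-frame when `(cds_start - p)` is a
#' multiple of 3.
#'
#' @param sequence transcript sequence (RNA or DNA alphabet).
#' @param cds_start 1-based position of the annotated CDS start codon.
#' @return named integer vector `in_frame`, `out_of_frame`.
#' @export
five_prime_aug_counts <- function(sequence, cds_start) {
  assert_that(cds_start >= 1, "cds_start must be >= 1")
  up <- chartr("T", "U", toupper(sequence))
  utr <- substr(up, 1, cds_start - 1)
  pos <- gregexpr("(?=AUG)", utr, perl = TRUE)[[1]]
  pos <- pos[pos > 0 & pos <= cds_start - 3]
  in_frame <- sum((cds_start - pos) %% 3 == 0)
  c(in_frame = in_frame, out_of_frame = length(pos) - in_frame)
}

#' Codon, wobble-base and dinucleotide frequencies of a CDS
#'
#' @param cds_seq in-frame coding sequence (length a multiple of 3).
#' @return list with `codon` (64 frequencies), `wobble` (third-position
#'   nucleotide frequencies), `dinucleotide` (16 frequencies).
#' @export
codon_features <- function(cds_seq) {
  up <- chartr("U", "T", toupper(cds_seq))
  n <- nchar(up) %/% 3
  assert_that(n >= 1, "CDS shorter than one codon")
  codons <- substring(up, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
  all_codons <- names(Biostrings::GENETIC_CODE)
  codon_freq <- table(factor(codons, levels = all_codons)) / n
  wob <- substr(codons, 3, 3)
  wobble <- table(factor(wob, levels = c("A", "C", "G", "T"))) / n
  names(wobble) <- c("A", "C", "G", "U")
  dinuc <- kmer_frequencies(up, 2)
  list(codon = stats::setNames(as.numeric(codon_freq),
                               chartr("T", "U", all_codons)),
       wobble = stats::setNames(as.numeric(wobble), names(wobble)),
       dinucleotide = dinuc)
}

#' MILC codon-usage distance
#'
#' Measure Independent of Length and Composition: for each gene,
#' `M = sum_a D_a / L - C`, where `D_a = 2 sum_{c in a} o_c log(f_c / g_c)`
#' compares the gene's within-amino-acid codon frequencies `f_c` with the
#' reference set's `g_c`, `L` is the gene's codon count, and
#' `C = sum_a (r_a - 1) / L - 0.5` corrects for length (with `r_a` the number
#' of synonymous codons of amino acids present in the gene). Lower values
#' mean codon usage closer to the reference; computed against a highly
#' expressed reference it is a codon-optimality score.
#'
#' @param cds_seqs character vector of in-frame coding sequences.
#' @param reference_seqs coding sequences defining the reference usage.
#' @return numeric MILC value per input sequence.
#' @export
milc_score <- function(cds_seqs, reference_seqs) {
  code <- Biostrings::GENETIC_CODE
  aa_of <- code[setdiff(names(code), c("TAA", "TAG", "TGA"))]
  codon_counts <- function(s) {
    up <- chartr("U", "T", toupper(s))
    n <- nchar(up) %/% 3
    codons <- substring(up, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
    table(factor(codons, levels = names(aa_of)))
  }
  # half-count pseudocount keeps reference frequencies positive for codons
  # the reference never uses, so divergence from them still registers
  ref <- Reduce(`+`, lapply(reference_seqs, codon_counts)) + 0.5
  ref_by_aa <- tapply(as.numeric(ref), aa_of, sum)
  g <- as.numeric(ref) / pmax(1e-12, ref_by_aa[aa_of])
  names(g) <- names(aa_of)
  vapply(cds_seqs, function(s) {
    o <- as.numeric(codon_counts(s))
    names(o) <- names(aa_of)
    n_by_aa <- tapply(o, aa_of, sum)
    f <- o / pmax(1e-12, n_by_aa[aa_of])
    L <- sum(o)
    nonzero <- o > 0 & g > 0
    d <- 2 * sum(o[nonzero] * log(f[nonzero] / g[nonzero]))
    present <- names(n_by_aa)[n_by_aa > 0]
    r <- table(aa_of)[present]
    correction <- sum(r - 1) / L - 0.5
    d / L - correction
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble the granule-relocalization feature matrix
#'
#' Builds the predictor matrix for modeling mRNA relocalization to granules:
#' log10 lengths (transcript, 5'/3' UTR, CDS), k-mer frequencies, AU
#' content, binary RBP-binding columns, optional binary annotation flags
#' (polyA, uORF, IRES, ...), in-frame and out-of-frame upstream-AUG counts,
#' codon / dinucleotide / wobble frequencies, a codon-optimality (MILC)
#' score, abundance, a one-hot encoding of the basal localization (argmax
#' proportion), and interactions of that one-hot with the length and RBP
#' features. Transcripts lacking CDS annotation get zero codon features and
#' a `no_cds` flag.
#'
#' @param feature_table tibble with `feature_id`, `length`, `au_content`,
#'   `abundance`, `utr5_length`, `cds_length`, `utr3_length` (UTR/CDS may be
#'   NA for non-coding transcripts).
#' @param sequences named character vector of transcript sequences.
#' @param proportions tibble `feature_id` + one proportion column per
#'   localization (basal condition); drives the one-hot encoding.
#' @param rbp_binding tibble `feature_id` + binary RBP columns (e.g. from
#'   [select_rbp_columns()]), or NULL.
#' @param flags tibble `feature_id` + binary columns (polyA/uORF/IRES...),
#'   or NULL.
#' @param kmer_k k-mer sizes to include (default 1:3).
#' @param milc_reference sequences for the MILC reference; default: all
#'   coding sequences in the input.
#' @return tibble `feature_id` + numeric predictor columns (no missing
#'   values).
#' @export
build_granule_features <- function(feature_table, sequences, proportions,
                                   rbp_binding = NULL, flags = NULL,
                                   kmer_k = 1:3, milc_reference = NULL) {
  ft <- feature_table[feature_table$feature_id %in% names(sequences), ]
  ids <- ft$feature_id
  seqs <- sequences[ids]
  out <- tibble::tibble(
    feature_id = ids,
    log10_length = log10(ft$length),
    log10_utr5 = log10(pmax(1, ifelse(is.na(ft$utr5_length), 1, ft$utr5_length))),
    log10_cds = log10(pmax(1, ifelse(is.na(ft$cds_length), 1, ft$cds_length))),
    log10_utr3 = log10(pmax(1, ifelse(is.na(ft$utr3_length), 1, ft$utr3_length))),
    au_content = ft$au_content,
    log10_abundance = log10(ft$abundance + 1)
  )
  for (k in kmer_k) {
    km <- kmer_frequency_matrix(seqs, k)
    colnames(km) <- paste0("kmer_", colnames(km))
    out <- dplyr::bind_cols(out, tibble::as_tibble(km, .name_repair = "minimal"))
  }

  has_cds <- !is.na(ft$cds_length) & !is.na(ft$utr5_length)
  cds_seq <- ifelse(has_cds,
                    substr(seqs, ft$utr5_length + 1,
                           ft$utr5_length + ft$cds_length),
                    "")
  aug <- t(vapply(seq_along(ids), function(i) {
    if (!has_cds[i]) return(c(in_frame = 0, out_of_frame = 0))
    five_prime_aug_counts(seqs[i], ft$utr5_length[i] + 1)
  }, numeric(2)))
  out$aug5_in_frame <- aug[, "in_frame"]
  out$aug5_out_of_frame <- aug[, "out_of_frame"]
  out$no_cds <- as.integer(!has_cds)

  codon_mat <- matrix(0, length(ids), 64 + 4 + 16)
  cf_names <- NULL
  for (i in which(has_cds)) {
    cf <- codon_features(cds_seq[i])
    v <- c(cf$codon, cf$wobble, cf$dinucleotide)
    if (is.null(cf_names)) {
      cf_names <- c(paste0("codon_", names(cf$codon)),
                    paste0("wobble_", names(cf$wobble)),
                    paste0("dinuc_", names(cf$dinucleotide)))
    }
    codon_mat[i, ] <- v
  }
  if (is.null(cf_names)) {
    cf_names <- paste0("codonfeat_", seq_len(ncol(codon_mat)))
  }
  colnames(codon_mat) <- cf_names
  out <- dplyr::bind_cols(out, tibble::as_tibble(codon_mat,
                                                 .name_repair = "minimal"))

  out$milc <- 0
  if (any(has_cds)) {
    refs <- milc_reference %||% cds_seq[has_cds]
    out$milc[has_cds] <- milc_score(cds_seq[has_cds], refs)
  }

  if (!is.null(flags)) {
    out <- dplyr::left_join(out, flags, by = "feature_id")
    flag_cols <- setdiff(names(flags), "feature_id")
    out[flag_cols][is.na(out[flag_cols])] <- 0
  }

  # one-hot basal localization by highest proportion
  pr <- proportions[match(ids, proportions$feature_id), , drop = FALSE]
  loc_cols <- setdiff(names(proportions), c("feature_id", "condition",
                                            "replicates_used"))
  pm <- as.matrix(pr[, loc_cols])
  pm[is.na(pm)] <- 0
  argmax <- loc_cols[max.col(pm, ties.method = "first")]
  onehot <- matrix(0L, length(ids), length(loc_cols),
                   dimnames = list(NULL, paste0("basal_", loc_cols)))
  onehot[cbind(seq_along(ids), match(argmax, loc_cols))] <- 1L
  out <- dplyr::bind_cols(out, tibble::as_tibble(onehot,
                                                 .name_repair = "minimal"))

  rbp_cols <- character(0)
  if (!is.null(rbp_binding)) {
    rb <- rbp_binding[match(ids, rbp_binding$feature_id), , drop = FALSE]
    rbp_cols <- setdiff(names(rbp_binding), "feature_id")
    rbm <- as.matrix(rb[, rbp_cols])
    rbm[is.na(rbm)] <- 0
    colnames(rbm) <- paste0("rbp_", rbp_cols)
    out <- dplyr::bind_cols(out, tibble::as_tibble(rbm,
                                                   .name_repair = "minimal"))
    rbp_cols <- colnames(rbm)
  }

  # interactions: basal localization x lengths, basal localization x RBPs
  base_feats <- c("log10_length", "log10_utr5", "log10_cds", "log10_utr3",
                  rbp_cols)
  for (loc in paste0("basal_", loc_cols)) {
    for (bf in base_feats) {
      out[[paste0(loc, "_x_", bf)]] <- out[[loc]] * out[[bf]]
    }
  }
  assert_that(!anyNA(out), "feature matrix contains missing values")
  out
}
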