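make_psms <- function(profiles, proteins, peptides = NULL, unique_flag = TRUE) {
  n <- nrow(profiles)
  colnames(profiles) <- paste0("channel_", seq_len(ncol(profiles)))
  tibble::tibble(
    psm_id = sprintf("P%03d", seq_len(n)),
    master_protein = proteins,
    peptide_seq = peptides %||% sprintf("PEP%03d", seq_len(n)),
    unique_flag = rep_len(unique_flag, n),
    tibble::as_tibble(profiles, .name_repair = "minimal")
  )
}

test_that("contaminants and peptide-sharing proteins are removed", {
  psms <- make_psms(matrix(1, 4, 4), c("crap1", "protA", "protA", "protB"),
                    peptides = c("AAA", "AAA", "BBB", "CCC"))
  out <- remove_contaminants(psms, "crap1")
  # protA shares peptide AAA with the cRAP protein: all its PSMs go
  expect_setequal(out$master_protein, "protB")
  expect_setequal(attr(out, "flagged_proteins"), "protA")
  rep_tab <- attr(out, "removal_report")
  expect_equal(rep_tab$n_psms, c(1L, 2L))
})

test_that("the PSM filter enforces unique masters and the 20% missing rule", {
  m <- matrix(1, 3, 10)
  m[1, 1:3] <- NA   # 30% missing -> removed
  m[2, 1:2] <- NA   # exactly 20% -> retained
  psms <- make_psms(m, c("p1", "p2", "p3"))
  psms$unique_flag[3] <- FALSE
  out <- filter_psms(psms)
  expect_equal(out$psm_id, "P002")
})

test_that("knn imputation works in normalized profile space", {
  # ten identical complete neighbors with value 0.1 in channel 4
  prof <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), 10), 10, byrow = TRUE) * 100
  target <- c(0.4, 0.3, 0.2, NA) * 50
  psms <- make_psms(rbind(prof, target), c(sprintf("n%02d", 1:10), "t"))
  out <- impute_knn(psms, k = 10)
  got <- as.numeric(out[11, paste0("channel_", 1:4)])
  # the imputed value in normalized space is the neighbors' 0.1;
  # de-normalization rescales by the row's observed total (45)
  expect_equal(got[1:3], c(0.4, 0.3, 0.2) * 50)
  expect_equal(got[4], 0.1 * 45, tolerance = 1e-9)
  # rows without missing values are untouched
  expect_equal(as.matrix(out[1:10, paste0("channel_", 1:4)]),
               as.matrix(psms[1:10, paste0("channel_", 1:4)]))
})

test_that("a two-row toy imputes the hand-computed neighbor value", {
  a <- c(2, 2, 4, 2)          # normalized (0.2, 0.2, 0.4, 0.2)
  b <- c(10, 10, NA, 10)      # observed total 30
  psms <- make_psms(rbind(a, b), c("x", "y"))
  out <- suppressWarnings(impute_knn(psms, k = 10))
  got <- as.numeric(out[2, paste0("channel_", 1:4)])
  # normalized neighbor value at the missing channel is 0.4; de-normalized:
  # filled row (1/3, 1/3, 0.4, 1/3) rescaled by observed total 30
  expect_equal(got, c(10, 10, 0.4 * 30, 10))
})

test_that("outlier PSMs are removed by the median-distance rule", {
  base <- c(0.7, 0.1, 0.1, 0.1)
  far <- c(0.1, 0.1, 0.1, 0.7)
  psms <- make_psms(rbind(base, base, base, base, far) * 100, rep("p", 5))
  out <- remove_outlier_psms(psms)
  expect_equal(attr(out, "outlier_psms"), "P005")
  expect_equal(nrow(out), 4)
  # all siblings within 0.1: nothing removed
  near <- rbind(base, base + c(0.02, 0, 0, -0.02), base) * 100
  out2 <- remove_outlier_psms(make_psms(near, rep("q", 3)))
  expect_equal(length(attr(out2, "outlier_psms")), 0)
  # two mutually distant PSMs: both removed
  two <- make_psms(rbind(c(0.6, 0.4, 0, 0), c(0.35, 0.4, 0.25, 0)) * 10,
                   rep("r", 2))
  out3 <- remove_outlier_psms(two)
  expect_equal(nrow(out3), 0)
  expect_equal(nrow(aggregate_proteins(out3)), 0) |> suppressWarnings()
})

test_that("median centering equalizes channel medians", {
  m <- rbind(c(1, 2, 4), c(2, 4, 8), c(3, 6, 12))
  psms <- make_psms(m, c("a", "b", "c"))
  out <- median_center(psms)
  mm <- as.matrix(out[, paste0("channel_", 1:3)])
  meds <- unname(apply(mm, 2, median))
  expect_equal(meds, rep(meds[1], 3), tolerance = 1e-12)
  # already-equal medians: unchanged
  m2 <- rbind(c(1, 1, 1), c(2, 2, 2))
  out2 <- median_center(make_psms(m2, c("a", "b")))
  expect_equal(as.matrix(out2[, paste0("channel_", 1:3)]),
               as.matrix(m2), ignore_attr = TRUE, tolerance = 1e-12)
  # single-PSM table: its row becomes the (equalized) channel medians
  out3 <- median_center(make_psms(matrix(c(1, 2, 4), 1), "solo"))
  v <- as.numeric(out3[1, paste0("channel_", 1:3)])
  expect_equal(v, rep(v[1], 3))
  expect_error(median_center(make_psms(rbind(c(0, 1, 1)), "z")), "median")
})

test_that("protein aggregation sums, filters and normalizes", {
  m <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(5, 5, 5, 5))
  psms <- make_psms(m, c("pA", "pA", "pB"))
  out <- suppressWarnings(aggregate_proteins(psms))
  expect_equal(out$protein, "pA")             # pB has a single PSM
  expect_equal(as.numeric(out[1, paste0("channel_", 1:4)]),
               rep(0.25, 4))
  expect_true(all(out$psm_count >= 2))
  # two identical PSMs: protein profile equals the normalized PSM profile
  m2 <- rbind(c(2, 2, 4, 2), c(2, 2, 4, 2))
  out2 <- aggregate_proteins(make_psms(m2, c("pC", "pC")))
  expect_equal(as.numeric(out2[1, paste0("channel_", 1:4)]),
               c(0.2, 0.2, 0.4, 0.2))
})

test_that("normalized protein profiles are invariant to PSM scaling", {
  # PSMs of one protein share a profile at different ionization scales;
  # rescaling any PSM by a positive constant leaves the normalized protein
  # profile unchanged
  prof <- c(0.5, 0.25, 0.15, 0.1)
  m <- rbind(prof * 10, prof * 80, prof * 3)
  psms <- make_psms(m, rep("pA", 3))
  cc <- paste0("channel_", 1:4)
  scaled <- psms
  scaled[2, cc] <- scaled[2, cc] * 37
  a <- aggregate_proteins(impute_knn(psms))
  b <- aggregate_proteins(impute_knn(scaled))
  expect_equal(as.matrix(a[, cc]), as.matrix(b[, cc]), tolerance = 1e-12)
  expect_equal(as.numeric(a[1, cc]), prof)
})

test_that("the full PSM pipeline removes exactly the planted artifacts", {
  ark <- test_archetypes(seed = 2)
  cfg <- sim_config(n_proteins = 150, psm_noise_sd = 0, missing_rate = 0,
                    seed = 13)
  sim <- simulate_psm_table(cfg, ark)
  res <- process_psm_table(sim$psm_table, sim$contaminant_ids)
  truth_flagged <- sim$protein_truth$protein[
    sim$protein_truth$shares_contaminant_peptide]
  expect_setequal(res$flagged_proteins, truth_flagged)
  truth_out <- sim$psm_truth$psm_id[sim$psm_truth$is_outlier]
  expect_setequal(res$outlier_psms, truth_out)
  p <- res$proteins
  mm <- as.matrix(p[, grep("^channel", names(p))])
  expect_true(all(abs(rowSums(mm) - 1) < 1e-9))
  expect_true(all(p$psm_count >= 2))
  expect_false(any(sim$contaminant_ids %in% p$protein))
})
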