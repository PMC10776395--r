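test_that("imputation-based selection recovers the rank of an exact low-rank matrix", {
  set.seed(42)
  w <- matrix(rgamma(90 * 3, 2), 90, 3)
  h <- matrix(rgamma(3 * 8, 2), 3, 8)
  x <- w %*% h
  model <- select_k_by_imputation(x, 2:6, seed = 1)
  expect_equal(model$k, 3)
  expect_equal(nrow(model$mse_curve), 5)
  # every rank >= 3 completes the exact matrix to solver precision; ranks
  # below leave an error orders of magnitude larger
  mse <- model$mse_curve$imputation_mse
  expect_gt(mse[1] / mse[2], 100)
  expect_lt(mse[2], min(mse) + 1e-4 * mean(x^2))
})

test_that("rank selection is deterministic and handles a single candidate", {
  set.seed(7)
  x <- matrix(rgamma(40 * 6, 2), 40, 6)
  a <- select_k_by_imputation(x, 2:4, seed = 9)
  b <- select_k_by_imputation(x, 2:4, seed = 9)
  expect_identical(a$k, b$k)
  expect_identical(a$w, b$w)
  single <- select_k_by_imputation(x, 3, seed = 9)
  expect_equal(single$k, 3)
  expect_equal(nrow(single$mse_curve), 1)
  expect_error(select_k_by_imputation(x - 10, 2:3), "non-negative")
})

test_that("a priori marker rules apply the published thresholds", {
  inputs <- list(
    nuclear_ratio = tibble::tibble(gene_id = c("g_nuc20", "g_nuc10"),
                                   ratio = c(20, 10)),
    nes_apex = tibble::tibble(gene_id = c("g_cyt", "g_not"),
                              enriched = c(TRUE, FALSE)),
    er_riboseq = tibble::tibble(gene_id = c("g_er", "g_er_nosp", "g_er_low"),
                                enrichment = c(1.5, 1.5, 1.2)),
    kdel_apex = tibble::tibble(gene_id = c("g_er", "g_er_nosp", "g_er_low"),
                               fold = c(10, 10, 10),
                               significant = TRUE),
    sp_tm = tibble::tibble(gene_id = c("g_er", "g_er_nosp", "g_er_low"),
                           has_sp_tm = c(TRUE, FALSE, TRUE)),
    mito_genes = c("mt1", "mt2"),
    manual_nuclear = "lnc_nuc"
  )
  mk <- define_apriori_markers(inputs)
  expect_setequal(mk$member_id[mk$localization == "nucleus"],
                  c("g_nuc20", "lnc_nuc"))          # 20-fold > 16, 10-fold not
  expect_setequal(mk$member_id[mk$localization == "cytosol"], "g_cyt")
  # ER needs riboseq > 2^0.5 AND significant 8-fold KDEL AND SP/TM
  expect_setequal(mk$member_id[mk$localization == "er"], "g_er")
  expect_setequal(mk$member_id[mk$localization == "mitochondria"],
                  c("mt1", "mt2"))
  # an empty localization errors
  inputs2 <- inputs
  inputs2$sp_tm$has_sp_tm <- FALSE
  expect_error(define_apriori_markers(inputs2), "no markers found")
})

test_that("clusters expand a priori markers and report novel profiles", {
  cl <- c(g1 = 1, g2 = 1, g3 = 1, g10 = 1, g11 = 1, g4 = 2, g5 = 2,
          n1 = 3, n2 = 3)
  model <- list(cluster = cl)
  apriori <- marker_set(c("g1", "g2", "g3", "g6", "g4", "g5"),
                        c(rep("nucleus", 4), rep("cytosol", 2)))
  out <- map_clusters_to_apriori(model, apriori)
  expect_setequal(out$markers$member_id[out$markers$localization == "nucleus"],
                  c("g1", "g2", "g3", "g10", "g11"))
  expect_setequal(out$markers$member_id[out$markers$localization == "cytosol"],
                  c("g4", "g5"))
  expect_equal(out$novel_clusters, list(cluster_3 = c("n1", "n2")))
  # expansion is monotone: a priori members inside their cluster remain
  expect_true(all(c("g1", "g2", "g3") %in% out$markers$member_id))
  # partition property: expanded sets + novel clusters = clustered features
  expect_setequal(c(out$markers$member_id, unlist(out$novel_clusters)),
                  names(cl))
  expect_equal(anyDuplicated(out$markers$member_id), 0L)
})

test_that("cluster mapping conflicts and ties are errors", {
  model <- list(cluster = c(a = 1, b = 1, c = 2, d = 2))
  both_same <- marker_set(c("a", "b"), c("nucleus", "cytosol"))
  expect_error(map_clusters_to_apriori(model, both_same), "same cluster")
  tie <- marker_set(c("a", "c"), c("nucleus", "nucleus"))
  expect_error(map_clusters_to_apriori(model, tie), "tie")
})

test_that("cytosol-light and nucleolus definitions are set operations", {
  expect_setequal(define_cytosol_light(c("a", "b", "c"), c("b", "c", "d")),
                  c("b", "c"))
  expect_warning(out <- define_cytosol_light(c("a"), c("b")), "empty")
  expect_length(out, 0)
  expect_setequal(define_cytosol_light(c("x", "y"), c("x", "y")), c("x", "y"))
  expect_setequal(define_nucleolus_markers(c("s1", "s2", "g1"),
                                           c("s1", "s2", "s3")), c("s1", "s2"))
  expect_length(define_nucleolus_markers(c("s1"), c("s1", "s2"), top_n = 0), 0)
  expect_length(define_nucleolus_markers(c("g1"), c("s1", "s2")), 0)
})

test_that("transcript extension respects biotype matching and the blacklist", {
  gene_mk <- marker_set("gene1", "er")
  ann <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    gene_id = "gene1",
    transcript_biotype = c("protein_coding", "retained_intron"),
    gene_biotype = "protein_coding"
  )
  tx <- extend_to_transcripts(gene_mk, ann)
  expect_equal(tx$member_id, "t1")
  # blacklisted member removed
  expect_message(tx2 <- extend_to_transcripts(gene_mk, ann, blacklist = "t1"),
                 "blacklisted")
  expect_equal(nrow(tx2), 0)
  # a gene with no matching-biotype isoform contributes nothing
  gene_mk2 <- marker_set(c("gene1", "gene2"), c("er", "er"))
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    transcript_id = "t3", gene_id = "gene2",
    transcript_biotype = "processed_transcript", gene_biotype = "lncRNA"))
  expect_equal(extend_to_transcripts(gene_mk2, ann2)$member_id, "t1")
})

test_that("a marker may belong to exactly one localization", {
  expect_error(marker_set(c("a", "a"), c("nucleus", "cytosol")),
               "multiple localizations")
  m <- marker_set(c("a", "a"), c("nucleus", "nucleus"))
  expect_equal(nrow(m), 1)
})

test_that("marker sets round-trip through TSV", {
  m <- marker_set(c("a", "b"), c("nucleus", "er"), provenance = "apriori")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_set(m, path)
  m2 <- read_marker_set(path)
  expect_equal(as.data.frame(m), as.data.frame(m2))
})
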