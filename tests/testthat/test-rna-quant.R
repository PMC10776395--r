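test_that("refractometer reading converts to iodixanol percentage", {
  expect_equal(iodixanol_from_refractive_index(8.39213), 0, tolerance = 1e-4)
  expect_equal(iodixanol_from_refractive_index(20.84213), 15, tolerance = 1e-4)
  expect_equal(iodixanol_from_refractive_index(9.222), 9.222 / 0.83 - 10.111)
  expect_error(iodixanol_from_refractive_index(NaN), "finite")
  expect_error(iodixanol_from_refractive_index(-1), "finite")
})

test_that("fraction content follows the endogenous:spike-in ratio", {
  tab <- toy_profile_table(matrix(c(900, 500), 1))
  sp <- list(spikein_total = c(100, 500), proportion_used = c(0.5, 0.5))
  expect_equal(unname(estimate_fraction_content(tab, sp)), c(0.9, 0.1))
  # identical ratios -> uniform
  sp2 <- list(spikein_total = c(90, 50), proportion_used = c(1, 1))
  expect_equal(unname(estimate_fraction_content(tab, sp2)), c(0.5, 0.5))
  # halving the proportion used doubles that fraction's content
  sp3 <- list(spikein_total = c(100, 500), proportion_used = c(0.25, 0.5))
  raw <- c(900 / 100 / 0.25, 500 / 500 / 0.5)
  expect_equal(unname(estimate_fraction_content(tab, sp3)), raw / sum(raw))
  sp4 <- list(spikein_total = c(100, 0), proportion_used = c(0.5, 0.5))
  expect_error(estimate_fraction_content(tab, sp4), "fraction\\(s\\): 2")
})

test_that("normalization content-adjusts then row-normalizes", {
  tab <- toy_profile_table(matrix(c(2, 2, 4, 2), 1))
  out <- normalize_profiles(tab, rep(0.25, 4))
  expect_equal(as.numeric(out[1, paste0("fraction_", 1:4)]),
               c(0.2, 0.2, 0.4, 0.2))
  # a row already summing to one with uniform content is unchanged
  tab2 <- toy_profile_table(matrix(c(0.2, 0.2, 0.4, 0.2), 1))
  out2 <- normalize_profiles(tab2, rep(1, 4))
  expect_equal(as.numeric(out2[1, paste0("fraction_", 1:4)]),
               c(0.2, 0.2, 0.4, 0.2))
  tab3 <- toy_profile_table(matrix(c(1, 1), 1))
  out3 <- normalize_profiles(tab3, c(0.75, 0.25))
  expect_equal(as.numeric(out3[1, paste0("fraction_", 1:2)]), c(0.75, 0.25))
  expect_error(normalize_profiles(tab3, c(-1, 2)), "negative content")
  # idempotence on row-normalized input with uniform content
  again <- normalize_profiles(out3, c(1, 1))
  expect_equal(as.data.frame(again), as.data.frame(out3))
})

test_that("content estimation ignores library-size rescaling of one fraction", {
  ds <- small_dataset()
  sub <- ds$rna_profiles[ds$rna_profiles$condition == "control" &
                           ds$rna_profiles$replicate == 1, ]
  sp <- ds$spikeins[ds$spikeins$condition == "control" &
                      ds$spikeins$replicate == 1, ]
  c1 <- estimate_fraction_content(sub, sp)
  sub2 <- sub
  sub2$fraction_3 <- sub2$fraction_3 * 7.5   # rescale one fraction's library
  sp2 <- sp
  sp2$spikein_total[3] <- sp2$spikein_total[3] * 7.5
  c2 <- estimate_fraction_content(toy_profile_table(as.matrix(sub2[, paste0("fraction_", 1:8)])), sp2)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("expression filter applies the mean and zero-share rules", {
  m <- rbind(c(0.6, 0.6, 0.0),   # mean 0.4 < 0.5 -> discarded
             c(1.0, 0.0, 0.0),   # zero in 2/3 samples -> discarded
             c(1.0, 1.0, 1.0))   # retained
  rows <- do.call(rbind, lapply(1:3, function(r) {
    tibble::tibble(feature_id = paste0("G", 1:3), biotype = "mRNA",
                   condition = "control", replicate = r,
                   fraction_1 = m[, r], fraction_2 = m[, r])
  }))
  tab <- profile_table(rows, state = "raw")
  out <- filter_low_abundance(tab, "control")
  expect_setequal(unique(out$feature_id), "G3")
  rep_tab <- attr(out, "filter_report")
  expect_equal(rep_tab$n[rep_tab$rule == "total_removed"], 2)
  # deterministic on reapplication
  out2 <- filter_low_abundance(tab, "control")
  expect_identical(as.data.frame(out), as.data.frame(out2))
})

test_that("lncRNAs with close protein-coding neighbors are excluded", {
  ann <- tibble::tibble(
    gene_id = c("lnc_down10", "lnc_up40", "lnc_overlap", "lnc_minus",
                "pc1", "pc2", "pc3", "pc4"),
    chrom = "chr1",
    start = c(100000, 200000, 300000, 400000,
              111000, 160000, 300500, 350500),
    end = c(101000, 201000, 301000, 401000,
            112000, 161000, 301500, 351500),
    strand = c("+", "+", "+", "-", "+", "+", "+", "+"),
    biotype = c(rep("lncRNA", 4), rep("protein_coding", 4))
  )
  feats <- c("lnc_down10", "lnc_up40", "lnc_overlap", "lnc_minus", "pc1")
  out <- exclude_neighbor_lncrnas(feats, ann)
  # pc1 is ~10 kb downstream of lnc_down10 (on +) -> excluded
  expect_false("lnc_down10" %in% out)
  # pc2 is ~39 kb upstream of lnc_up40 -> retained
  expect_true("lnc_up40" %in% out)
  # overlapping protein-coding gene -> excluded
  expect_false("lnc_overlap" %in% out)
  # minus strand: pc4 ends ~48.5 kb to the genomic left of lnc_minus, which
  # is downstream in transcript orientation and beyond 15 kb -> retained
  expect_true("lnc_minus" %in% out)
  # protein-coding features are untouched
  expect_true("pc1" %in% out)
  ann_bad <- ann
  ann_bad$strand[1] <- "*"
  expect_error(exclude_neighbor_lncrnas(feats, ann_bad), "strand")
})

test_that("minus-strand windows use transcript orientation", {
  # protein-coding gene 10 kb to the genomic RIGHT of a minus-strand lncRNA
  # is 10 kb UPSTREAM in transcript orientation -> inside the 30 kb window
  ann <- tibble::tibble(
    gene_id = c("lncA", "pcA"), chrom = "chr2",
    start = c(100000, 111000), end = c(101000, 112000),
    strand = c("-", "+"), biotype = c("lncRNA", "protein_coding")
  )
  expect_false("lncA" %in% exclude_neighbor_lncrnas("lncA", ann))
  # at 40 kb right it is outside the upstream window
  ann$start[2] <- 141000; ann$end[2] <- 142000
  expect_true("lncA" %in% exclude_neighbor_lncrnas("lncA", ann))
  # 20 kb to the genomic LEFT = 20 kb downstream on minus strand -> outside
  # the 15 kb downstream window
  ann$start[2] <- 79000; ann$end[2] <- 80000
  expect_true("lncA" %in% exclude_neighbor_lncrnas("lncA", ann))
  # 10 kb left = 10 kb downstream -> excluded
  ann$start[2] <- 89000; ann$end[2] <- 90000
  expect_false("lncA" %in% exclude_neighbor_lncrnas("lncA", ann))
})
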