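basis_2x4 <- function() {
  b <- rbind(A = c(1, 0, 0, 0), B = c(0, 0, 0.5, 0.5))
  colnames(b) <- paste0("fraction_", 1:4)
  b
}

test_that("marker basis rows are mean row-normalized marker profiles", {
  m <- rbind(m1 = c(1, 0, 0, 0), m2 = c(0.8, 0.2, 0, 0),
             c1 = c(0, 0, 0.5, 0.5))
  colnames(m) <- paste0("fraction_", 1:4)
  mk <- marker_set(c("m1", "m2", "c1"), c("mem", "mem", "cyt"))
  basis <- build_marker_basis(m, mk, mode = "sedimentation")
  expect_equal(unname(basis$basis["mem", ]), c(0.9, 0.1, 0, 0))
  expect_equal(unname(basis$basis["cyt", ]), c(0, 0, 0.5, 0.5))
  # one marker per class: basis row equals that marker's profile
  basis1 <- build_marker_basis(m[c("m1", "c1"), ],
                               marker_set(c("m1", "c1"), c("mem", "cyt")),
                               mode = "sedimentation")
  expect_equal(unname(basis1$basis["mem", ]), c(1, 0, 0, 0))
  # two identical markers: mean equals either
  m2 <- rbind(a = c(0.5, 0.5, 0, 0), b = c(0.5, 0.5, 0, 0),
              c1 = c(0, 0, 0.5, 0.5))
  colnames(m2) <- colnames(m)
  basis2 <- build_marker_basis(m2, marker_set(c("a", "b", "c1"),
                                              c("mem", "mem", "cyt")),
                               mode = "sedimentation")
  expect_equal(unname(basis2$basis["mem", ]), c(0.5, 0.5, 0, 0))
})

test_that("density mode drops the ER class and anchors membrane on mitochondria", {
  ds <- small_dataset()
  content <- estimate_content_by_library(ds$rna_profiles, ds$spikeins)
  norm <- normalize_profiles(ds$rna_profiles, content)
  basis <- build_marker_basis(norm, ds$markers, mode = "density",
                              condition = "control")
  expect_false("er" %in% basis$localizations)
  expect_true("membrane" %in% basis$localizations)
  expect_false("mitochondria" %in% basis$localizations)
  sed <- build_marker_basis(norm, ds$markers, mode = "sedimentation",
                            condition = "control")
  expect_true(all(c("er", "mitochondria") %in% sed$localizations))
})

test_that("exact mixtures are recovered exactly", {
  b <- basis_2x4()
  y <- 0.4 * b["A", ] + 0.6 * b["B", ]
  fit <- estimate_proportions(y, b)
  expect_equal(unname(fit$proportions), c(0.4, 0.6), tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$qc_pass)
  # profile equal to one basis row
  fit2 <- estimate_proportions(b["A", ], b)
  expect_equal(unname(fit2$proportions), c(1, 0), tolerance = 1e-9)
  expect_error(estimate_proportions(rep(0, 4), b), "all-zero")
})

test_that("random noiseless mixtures over the full basis are identified", {
  ark <- test_archetypes()
  b <- ark$profiles
  set.seed(11)
  for (i in 1:25) {
    p <- as.numeric(rmultinom(1, 20, rep(1, 6))) / 20
    y <- as.numeric(p %*% b)
    fit <- estimate_proportions(y, b)
    expect_equal(unname(fit$proportions), p, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("a poorly explained profile fails QC and matches the grid oracle", {
  b <- basis_2x4()
  y <- c(0, 1, 0, 0)
  fit <- estimate_proportions(y, b)
  expect_false(fit$qc_pass)
  expect_lt(fit$r_squared, 0.90)
  oracle <- grid_nnls_oracle(y, b)
  expect_lt(max(abs(unname(fit$proportions) - oracle$p)), 0.011)
  expect_lt(abs(fit$intercept - oracle$c), 0.011)
})

test_that("the solver agrees with the grid oracle on random two-class toys", {
  set.seed(3)
  b <- basis_2x4()
  for (i in 1:5) {
    y <- runif(4)
    y <- y / sum(y)
    fit <- estimate_proportions(y, b)
    oracle <- grid_nnls_oracle(y, b)
    expect_lte(sum((y - (fit$proportions[1] * b[1, ] +
                           fit$proportions[2] * b[2, ] + fit$intercept))^2),
               oracle$sse + 1e-9)
    expect_lt(max(abs(unname(fit$proportions) - oracle$p)), 0.011)
  }
})

test_that("the mitochondrial marker mean profile deconvolves to pure membrane", {
  ds <- small_dataset()
  content <- estimate_content_by_library(ds$rna_profiles, ds$spikeins)
  norm <- normalize_profiles(ds$rna_profiles, content)
  basis <- build_marker_basis(norm, ds$markers, mode = "density",
                              condition = "control")
  m <- mean_feature_profiles(norm, "control")
  mito <- ds$markers$member_id[ds$markers$localization == "mitochondria"]
  mito_mean <- colMeans(m[intersect(mito, rownames(m)), ])
  fit <- estimate_proportions(mito_mean / sum(mito_mean), basis)
  expect_equal(unname(fit$proportions["membrane"]), 1, tolerance = 1e-6)
  expect_equal(unname(sum(fit$proportions) - fit$proportions["membrane"]), 0,
               tolerance = 1e-6)
})

test_that("bootstrap intervals behave and are reproducible", {
  m <- rbind(a = c(1, 0, 0, 0), b = c(1, 0, 0, 0),
             c1 = c(0, 0, 0.5, 0.5), c2 = c(0, 0, 0.5, 0.5))
  colnames(m) <- paste0("fraction_", 1:4)
  mk <- marker_set(rownames(m), c("mem", "mem", "cyt", "cyt"))
  y <- 0.3 * m["a", ] + 0.7 * m["c1", ]
  bs <- bootstrap_proportions(y, m, mk, B = 25, seed = 1,
                              mode = "sedimentation")
  # all markers identical within class: interval width zero
  expect_equal(bs$lower, bs$upper, tolerance = 1e-12)
  expect_equal(bs$estimate[bs$localization == "mem"], 0.3, tolerance = 1e-9)
  bs2 <- bootstrap_proportions(y, m, mk, B = 25, seed = 1,
                               mode = "sedimentation")
  expect_identical(bs, bs2)
  expect_error(bootstrap_proportions(y, m, mk, B = 0), "B must be")
})

test_that("bootstrap intervals usually cover the full-marker point estimate", {
  ds <- small_dataset()
  content <- estimate_content_by_library(ds$rna_profiles, ds$spikeins)
  norm <- normalize_profiles(ds$rna_profiles, content)
  m <- mean_feature_profiles(norm, "control")
  set.seed(5)
  feats <- sample(setdiff(rownames(m), ds$markers$member_id), 20)
  covered <- vapply(feats, function(f) {
    bs <- bootstrap_proportions(m[f, ], m, ds$markers, B = 60, seed = 2,
                                mode = "sedimentation")
    all(bs$estimate >= bs$lower - 1e-9 & bs$estimate <= bs$upper + 1e-9)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("replicate averaging enforces the 2-of-3 rule", {
  est <- tibble::tibble(
    feature_id = rep(c("f1", "f2"), each = 3),
    condition = "control",
    replicate = rep(1:3, 2),
    mem = c(0.2, 0.4, 0.9, 0.5, 0.6, 0.7),
    cyt = c(0.8, 0.6, 0.1, 0.5, 0.4, 0.3),
    intercept = 0, r_squared = 1,
    qc_pass = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    qc_reason = NA_character_
  )
  out <- suppressMessages(average_replicates(est))
  expect_equal(out$feature_id, "f1")      # f2 passes only once -> dropped
  expect_equal(out$mem, 0.3)              # mean of passing replicates 1 and 2
  expect_equal(out$replicates_used, 2L)
  norm <- suppressMessages(average_replicates(est, normalized = TRUE))
  expect_equal(norm$mem_norm + norm$cyt_norm, 1)
})

test_that("relocalization deltas difference matched features only", {
  ctrl <- tibble::tibble(feature_id = c("a", "b"), condition = "control",
                         granule = c(0.1, 0.5), replicates_used = 3L)
  upr <- tibble::tibble(feature_id = c("a", "c"), condition = "upr",
                        granule = c(0.4, 0.2), replicates_used = 3L)
  out <- suppressMessages(relocalization_delta(ctrl, upr, "granule"))
  expect_equal(out$feature_id, "a")
  expect_equal(out$delta, 0.3)
  same <- suppressMessages(relocalization_delta(ctrl, ctrl, "granule"))
  expect_equal(same$delta, c(0, 0))
})

test_that("proportions convert to antisymmetric log2 enrichments", {
  expect_equal(proportion_to_enrichment(0.5), 0)
  expect_equal(proportion_to_enrichment(0.8), 2)
  expect_equal(proportion_to_enrichment(0.2), -2)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(proportion_to_enrichment(p), -proportion_to_enrichment(1 - p))
  expect_error(proportion_to_enrichment(1), "cap")
  expect_error(proportion_to_enrichment(1.2), "\\[0, 1\\]")
  expect_equal(proportion_to_enrichment(1, cap = 10), 10)
})
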