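#' Build the marker basis for proportion deconvolution
#'
#' Each basis row is the mean row-normalized profile of one localization's
#' markers. In `density` mode the ER marker class is excluded (ER markers
#' relocalize under stress, and the density gradient does not separate ER
#' from mitochondria) and the mitochondrial class is relabeled `membrane`: the
#' mitochondrially encoded transcripts have no cytosolic copies, so their
#' profile anchors 100% membrane localization. In `sedimentation` mode
#' mitochondria and ER stay separate basis rows; membrane proportions are
#' their sum downstream.
#'
#' @param profiles row-normalized [profile_table()], or directly a
#'   feature x fraction matrix of row-normalized profiles.
#' @param markers a [marker_set()].
#' @param mode "density" or "sedimentation".
#' @param condition condition whose profiles enter the basis (tables only).
#' @param membrane_class marker class anchoring membrane in density mode.
#' @param exclude_classes classes dropped from the basis in density mode.
#' @return a `gradloc_basis` object: `basis` (localization x fraction),
#'   `localizations`, `mode`, `membrane_reference`, `condition_number`.
#' @export
build_marker_basis <- function(profiles, markers,
                               mode = c("density", "sedimentation"),
                               condition = NULL,
                               membrane_class = "mitochondria",
                               exclude_classes = "er") {
  mode <- match.arg(mode)
  m <- if (is.matrix(profiles)) {
    row_normalize(profiles)
  } else {
    mean_feature_profiles(profiles, condition)
  }
  classes <- split(markers$member_id, markers$localization)
  if (mode == "density") {
    classes <- classes[setdiff(names(classes), exclude_classes)]
  }
  basis <- t(vapply(names(classes), function(loc) {
    members <- intersect(classes[[loc]], rownames(m))
    assert_that(length(members) > 0,
                sprintf("no profiled markers for localization '%s'", loc))
    colMeans(m[members, , drop = FALSE])
  }, numeric(ncol(m))))
  basis <- row_normalize(basis)
  if (mode == "density" && membrane_class %in% rownames(basis)) {
    rownames(basis)[rownames(basis) == membrane_class] <- "membrane"
    membrane_reference <- "membrane"
  } else {
    membrane_reference <- intersect(membrane_class, rownames(basis))
  }
  kappa <- kappa(basis, exact = TRUE)
  if (kappa > 1e6) {
    rlang::warn(sprintf("marker basis is ill-conditioned (condition number %.3g)",
                        kappa))
  }
  structure(list(basis = basis, localizations = rownames(basis), mode = mode,
                 membrane_reference = membrane_reference,
                 condition_number = kappa),
            class = "gradloc_basis")
}

#' @export
print.gradloc_basis <- function(x, ...) {
  cat(sprintf("<gradloc_basis> mode: %s, membrane reference: %s\n", x$mode,
              paste(x$membrane_reference, collapse = "+")))
  print(round(x$basis, 3))
  invisible(x)
}

#' Estimate localization proportions for one profile
#'
#' Models a row-normalized fraction profile as a non-negative linear
#' combination of the marker mean profiles plus a sign-unconstrained
#' intercept: `min || x - (sum_l p_l b_l + c 1) ||^2` with `p_l >= 0`. The
#' intercept is realized inside the non-negative solver by augmenting the
#' design with +1 and -1 columns. Fit quality is summarized by
#' `R^2 = 1 - SS_res / SS_tot` (total sum of squares about the profile mean);
#' the estimate passes QC iff `R^2 >= r2_min` and `|c| <= intercept_max`.
#'
#' @param profile_row numeric profile (row-normalized; any non-negative,
#'   not-all-zero vector is accepted and normalized).
#' @param basis a [build_marker_basis()] object (or bare matrix).
#' @param r2_min minimum variance explained (default 0.90).
#' @param intercept_max maximum absolute intercept (default 0.05).
#' @return list: `proportions` (named, >= 0), `intercept`, `r_squared`,
#'   `qc_pass`, `qc_reason`.
#' @export
estimate_proportions <- function(profile_row, basis, r2_min = 0.90,
                                 intercept_max = 0.05) {
  b <- if (inherits(basis, "gradloc_basis")) basis$basis else basis
  y <- as.numeric(profile_row)
  assert_that(length(y) == ncol(b),
              "profile length does not match basis fraction count")
  assert_that(all(y >= 0), "profile must be non-negative")
  assert_that(sum(y) > 0, "all-zero profile")
  y <- y / sum(y)
  design <- cbind(t(b), `+1` = 1, `-1` = -1)
  fit <- pracma::lsqnonneg(design, y)
  coefs <- fit$x
  p <- coefs[seq_len(nrow(b))]
  names(p) <- rownames(b)
  intercept <- coefs[nrow(b) + 1] - coefs[nrow(b) + 2]
  resid <- y - design %*% coefs
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  reason <- character(0)
  if (r2 < r2_min) reason <- c(reason, sprintf("R2 %.3f < %.2f", r2, r2_min))
  if (abs(intercept) > intercept_max) {
    reason <- c(reason, sprintf("|intercept| %.3f > %.2f", abs(intercept),
                                intercept_max))
  }
  list(proportions = p, intercept = unname(intercept), r_squared = r2,
       qc_pass = length(reason) == 0,
       qc_reason = if (length(reason)) paste(reason, collapse = "; ") else NA_character_)
}

#' Deconvolve every profile of a table
#'
#' Applies [estimate_proportions()] per feature x condition x replicate row of
#' a row-normalized profile table.
#'
#' @param profiles row-normalized [profile_table()].
#' @param basis a [build_marker_basis()] object.
#' @inheritParams estimate_proportions
#' @return tibble: feature_id, condition, replicate, one proportion column
#'   per localization, intercept, r_squared, qc_pass, qc_reason.
#' @export
deconvolve_profiles <- function(profiles, basis, r2_min = 0.90,
                                intercept_max = 0.05) {
  assert_that(profile_state(profiles) == "row_normalized",
              "profiles must be row_normalized")
  m <- fraction_matrix(profiles)
  fits <- lapply(seq_len(nrow(m)), function(i) {
    estimate_proportions(m[i, ], basis, r2_min, intercept_max)
  })
  props <- do.call(rbind, lapply(fits, `[[`, "proportions"))
  tibble::tibble(
    feature_id = profiles$feature_id,
    condition = profiles$condition,
    replicate = profiles$replicate,
    tibble::as_tibble(props, .name_repair = "minimal"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    qc_pass = vapply(fits, `[[`, logical(1), "qc_pass"),
    qc_reason = vapply(fits, `[[`, character(1), "qc_reason")
  )
}

#' Bootstrap intervals for localization proportions
#'
#' Resamples each marker class with replacement (same size as the class,
#' preserving class balance), rebuilds the basis, re-estimates the
#' proportions, and summarizes the B resamples by mean and percentile
#' interval per localization.
#'
#' @param profile_row profile to deconvolve.
#' @param profiles row-normalized [profile_table()] or feature x fraction
#'   matrix holding the marker profiles.
#' @param markers a [marker_set()].
#' @param B bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param level interval coverage (default 0.95).
#' @inheritParams build_marker_basis
#' @return tibble: localization, estimate (full-marker point estimate), mean,
#'   lower, upper.
#' @export
bootstrap_proportions <- function(profile_row, profiles, markers, B = 100,
                                  seed = 1L, level = 0.95,
                                  mode = "density", condition = NULL,
                                  membrane_class = "mitochondria",
                                  exclude_classes = "er") {
  assert_that(B >= 1, "B must be >= 1")
  m <- if (is.matrix(profiles)) {
    row_normalize(profiles)
  } else {
    mean_feature_profiles(profiles, condition)
  }
  full_basis <- build_marker_basis(m, markers, mode = mode,
                                   membrane_class = membrane_class,
                                   exclude_classes = exclude_classes)
  point <- estimate_proportions(profile_row, full_basis)$proportions
  classes <- split(markers$member_id, markers$localization)
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      res <- dplyr::bind_rows(lapply(names(classes), function(loc) {
        ids <- intersect(classes[[loc]], rownames(m))
        tibble::tibble(member_id = sample(ids, length(ids), replace = TRUE),
                       localization = loc)
      }))
      # resampled ids repeat: average duplicated rows by building the basis
      # mean over the resample directly
      basis <- t(vapply(split(res$member_id, res$localization), function(ids) {
        colMeans(m[ids, , drop = FALSE])
      }, numeric(ncol(m))))
      basis <- row_normalize(basis)
      if (full_basis$mode == "density") {
        basis <- basis[setdiff(rownames(basis), exclude_classes), , drop = FALSE]
        rownames(basis)[rownames(basis) == membrane_class] <- "membrane"
      }
      estimate_proportions(profile_row,
                           basis[full_basis$localizations, , drop = FALSE]
                           )$proportions
    }, numeric(length(point)))
  })
  alpha <- (1 - level) / 2
  tibble::tibble(
    localization = names(point),
    estimate = unname(point),
    boot_mean = rowMeans(draws),
    lower = apply(draws, 1, quantile, probs = alpha),
    upper = apply(draws, 1, quantile, probs = 1 - alpha)
  )
}

#' Average proportion estimates across replicates
#'
#' Keeps, per feature and condition, the mean proportions over replicates
#' that passed QC, for features with at least `min_replicates` passing
#' replicates; others are dropped (count reported via a message).
#'
#' @param estimates output of [deconvolve_profiles()].
#' @param min_replicates minimum passing replicates (default 2).
#' @param normalized also add a `*_norm` view rescaled to sum 1 per row.
#' @return tibble: feature_id, condition, proportions, replicates_used.
#' @export
average_replicates <- function(estimates, min_replicates = 2,
                               normalized = FALSE) {
  loc_cols <- setdiff(names(estimates),
                      c("feature_id", "condition", "replicate", "intercept",
                        "r_squared", "qc_pass", "qc_reason"))
  passing <- estimates[estimates$qc_pass, , drop = FALSE]
  out <- passing |>
    dplyr::group_by(.data$feature_id, .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(loc_cols), mean),
                     replicates_used = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$replicates_used >= min_replicates)
  n_dropped <- nrow(dplyr::distinct(estimates[, c("feature_id", "condition")])) -
    nrow(out)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "%d feature x condition estimates dropped (fewer than %d passing replicates)",
      n_dropped, min_replicates))
  }
  if (normalized) {
    s <- rowSums(out[, loc_cols])
    for (lc in loc_cols) out[[paste0(lc, "_norm")]] <- out[[lc]] / s
  }
  out
}

#' Per-feature change in a localization's proportion between conditions
#'
#' `delta = p(condition2) - p(condition1)`, computed on the raw
#' (unnormalized) proportions; features missing from either condition are
#' excluded (count reported via a message).
#'
#' @param table_control,table_stress outputs of [average_replicates()] for
#'   the two conditions.
#' @param localization which localization's proportion to difference.
#' @return tibble: feature_id, delta.
#' @export
relocalization_delta <- function(table_control, table_stress, localization) {
  assert_that(localization %in% names(table_control) &&
                localization %in% names(table_stress),
              sprintf("localization '%s' not present in both tables", localization))
  joined <- dplyr::inner_join(
    table_control[, c("feature_id", localization)],
    table_stress[, c("feature_id", localization)],
    by = "feature_id", suffix = c("_control", "_stress")
  )
  n_lost <- length(union(table_control$feature_id, table_stress$feature_id)) -
    nrow(joined)
  if (n_lost > 0) {
    rlang::inform(sprintf("%d features absent from one condition, excluded", n_lost))
  }
  tibble::tibble(
    feature_id = joined$feature_id,
    delta = joined[[paste0(localization, "_stress")]] -
      joined[[paste0(localization, "_control")]]
  )
}

#' Convert a localization proportion to a log2 enrichment
#'
#' `log2(p / (1 - p))` — the log-odds scale on which targeted enrichment
#' methods report localization, enabling comparison with proportion-based
#' estimates.
#'
#' @param p proportions in `[0, 1)`; `p = 1` is an error unless `cap` is set.
#' @param cap optional maximum |log2 enrichment| used to clip `p = 0` or
#'   `p = 1` instead of erroring.
#' @return log2 enrichment values.
#' @export
proportion_to_enrichment <- function(p, cap = NULL) {
  assert_that(all(p >= 0 & p <= 1), "proportions must lie in [0, 1]")
  if (is.null(cap)) {
    assert_that(all(p < 1), "p = 1 gives infinite enrichment (set `cap` to clip)")
    log2(p / (1 - p))
  } else {
    pmin(pmax(log2(p / (1 - p)), -cap), cap)
  }
}
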