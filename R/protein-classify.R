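#' Marker-based protein localization classification by SVM
#'
#' Repeated stratified train/test evaluation of a radial-basis support vector
#' machine on marker protein profiles: per iteration the markers are split
#' 80:20 within each class, hyperparameters (cost, gamma) are grid-searched
#' by cross-validation on the training markers, and per-class F1 is scored on
#' the held-out markers. A final model trained on all markers predicts the
#' localization of unlabeled proteins.
#'
#' @param profiles protein x fraction matrix of row-normalized profiles
#'   (rownames = protein ids).
#' @param protein_markers tibble `protein`, `localization` (markers must be
#'   rows of `profiles`).
#' @param iterations evaluation iterations (default 50).
#' @param seed integer seed.
#' @param cost,gamma hyperparameter grids.
#' @param min_class_size smallest admissible marker class (default 6).
#' @return a `gradloc_svm` list: `f1` (tibble iteration, localization, f1),
#'   `best_params`, `predictions` (tibble protein, predicted, score for
#'   non-marker proteins).
#' @export
classify_markers_svm <- function(profiles, protein_markers, iterations = 50,
                                 seed = 1L,
                                 cost = 2^(0:6), gamma = 2^(-4:1),
                                 min_class_size = 6) {
  assert_that(is.matrix(profiles), "profiles must be a matrix")
  mk <- protein_markers[protein_markers$protein %in% rownames(profiles), ]
  counts <- table(mk$localization)
  assert_that(length(counts) >= 2, "need >= 2 marker classes")
  small <- names(counts)[counts < min_class_size]
  assert_that(length(small) == 0,
              paste0("marker class(es) too small to split: ",
                     paste(small, collapse = ", ")))
  x <- profiles[mk$protein, , drop = FALSE]
  y <- factor(mk$localization)

  per_class_f1 <- function(truth, pred) {
    vapply(levels(truth), function(cl) {
      tp <- sum(pred == cl & truth == cl)
      prec <- if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl)
      rec <- if (sum(truth == cl) == 0) 0 else tp / sum(truth == cl)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
  }

  res <- with_seed(seed, {
    grid <- expand.grid(cost = cost, gamma = gamma)
    f1_rows <- list()
    best_rows <- list()
    for (it in seq_len(iterations)) {
      test_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
        sample(ix, max(1, round(0.2 * length(ix))))
      }))
      train_idx <- setdiff(seq_along(y), test_idx)
      cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
        fit <- e1071::svm(x[train_idx, , drop = FALSE],
                          droplevels(y[train_idx]),
                          cost = grid$cost[g], gamma = grid$gamma[g],
                          kernel = "radial", cross = 5)
        fit$tot.accuracy
      }, numeric(1))
      gbest <- which.max(cv_acc)
      fit <- e1071::svm(x[train_idx, , drop = FALSE],
                        droplevels(y[train_idx]),
                        cost = grid$cost[gbest], gamma = grid$gamma[gbest],
                        kernel = "radial")
      pred <- predict(fit, x[test_idx, , drop = FALSE])
      f1 <- per_class_f1(factor(y[test_idx], levels = levels(y)),
                         factor(pred, levels = levels(y)))
      f1_rows[[it]] <- tibble::tibble(iteration = it,
                                      localization = names(f1), f1 = f1)
      best_rows[[it]] <- tibble::tibble(iteration = it,
                                        cost = grid$cost[gbest],
                                        gamma = grid$gamma[gbest])
    }
    best <- dplyr::bind_rows(best_rows)
    final_cost <- as.numeric(names(sort(table(best$cost), decreasing = TRUE)[1]))
    final_gamma <- as.numeric(names(sort(table(best$gamma), decreasing = TRUE)[1]))
    final <- e1071::svm(x, y, cost = final_cost, gamma = final_gamma,
                        kernel = "radial", probability = TRUE)
    unl <- setdiff(rownames(profiles), mk$protein)
    preds <- if (length(unl) > 0) {
      pr <- predict(final, profiles[unl, , drop = FALSE], probability = TRUE)
      prob <- attr(pr, "probabilities")
      tibble::tibble(protein = unl, predicted = as.character(pr),
                     score = apply(prob, 1, max))
    } else {
      tibble::tibble(protein = character(0), predicted = character(0),
                     score = numeric(0))
    }
    list(f1 = dplyr::bind_rows(f1_rows),
         best_params = c(cost = final_cost, gamma = final_gamma),
         predictions = preds)
  })
  structure(res, class = "gradloc_svm")
}

#' Select exclusively nuclear proteins from localization scores
#'
#' Proteins with a knowledge-base confidence score of 5 for the nucleus and
#' no score over 2 for any other localization.
#'
#' @param score_table tibble with `protein`, a `Nucleus` column and one
#'   column per other localization (scores 0-5).
#' @return character protein ids.
#' @export
select_exclusive_nuclear <- function(score_table) {
  others <- setdiff(names(score_table), c("protein", "Nucleus"))
  other_max <- if (length(others) > 0) {
    do.call(pmax, c(score_table[others], na.rm = TRUE))
  } else {
    rep(0, nrow(score_table))
  }
  score_table$protein[score_table$Nucleus == 5 & other_max <= 2]
}

#' Split exclusively nuclear proteins into profile groups
#'
#' Applies, in order and first-match-wins, the profile thresholds that
#' separate nucleolus-associated from nucleoplasm proteins: group 1 has over
#' 0.3 of its normalized abundance in fraction 4, group 2 over 0.2 in
#' fraction 5, group 3 over 0.4 in fraction 8.
#'
#' @param profiles protein x fraction matrix of row-sum-normalized profiles
#'   with >= 8 fractions.
#' @param candidates protein ids to split (must be rows of `profiles`).
#' @return list with `group1`, `group2`, `group3`, `unassigned`.
#' @export
split_nuclear_groups <- function(profiles, candidates) {
  assert_that(ncol(profiles) >= 8, "profiles need >= 8 fractions")
  candidates <- intersect(candidates, rownames(profiles))
  p <- profiles[candidates, , drop = FALSE]
  g1 <- p[, 4] > 0.3
  g2 <- !g1 & p[, 5] > 0.2
  g3 <- !g1 & !g2 & p[, 8] > 0.4
  list(group1 = candidates[g1], group2 = candidates[g2],
       group3 = candidates[g3], unassigned = candidates[!(g1 | g2 | g3)])
}

#' Assign a localization from posterior probabilities
#'
#' A protein is assigned to a localization only when the posterior
#' localization probability, discounted by the outlier probability, clears
#' the threshold: `p_loc * (1 - p_out) > threshold`; otherwise the
#' localization is `"undefined"`.
#'
#' @param localization candidate localization name(s).
#' @param p_loc localization probability in `[0, 1]`.
#' @param p_out outlier probability in `[0, 1]`.
#' @param threshold assignment threshold (default 0.95).
#' @return character: the localization or "undefined" (vectorized).
#' @export
assign_localization <- function(localization, p_loc, p_out, threshold = 0.95) {
  assert_that(all(p_loc >= 0 & p_loc <= 1) && all(p_out >= 0 & p_out <= 1),
              "probabilities must lie in [0, 1]")
  ifelse(p_loc * (1 - p_out) > threshold, localization, "undefined")
}

#' Tiered differential-localization calls
#'
#' A protein is differentially localized when it is never assigned the same
#' localization across the two conditions (in any replicate) and at least 2
#' of 3 replicates have a differential-localization probability over the tier
#' threshold: >= 0.99 "highly_confident", >= 0.95 "confident", >= 0.85
#' "candidate"; otherwise "none".
#'
#' @param calls tibble with one row per protein x replicate: `protein`,
#'   `replicate`, `loc_control`, `loc_stress` (assigned localizations,
#'   possibly "undefined") and `p_dl` (differential-localization
#'   probability).
#' @param min_replicates replicates that must clear a tier threshold
#'   (default 2).
#' @param tiers named thresholds, checked from most to least stringent.
#' @return tibble: protein, tier, n_over_threshold (at the awarded tier),
#'   never_same_localization.
#' @export
call_differential_localization <- function(calls, min_replicates = 2,
                                           tiers = c(highly_confident = 0.99,
                                                     confident = 0.95,
                                                     candidate = 0.85)) {
  assert_that(all(calls$p_dl >= 0 & calls$p_dl <= 1),
              "p_dl must lie in [0, 1]")
  tiers <- sort(tiers, decreasing = TRUE)
  calls |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      never_same = !any(.data$loc_control == .data$loc_stress &
                          .data$loc_control != "undefined"),
      tier = {
        hit <- vapply(tiers, function(t) sum(.data$p_dl >= t), numeric(1))
        ok <- hit >= min_replicates
        if (never_same && any(ok)) names(tiers)[which(ok)[1]] else "none"
      },
      n_over_threshold = {
        hit <- vapply(tiers, function(t) sum(.data$p_dl >= t), numeric(1))
        ok <- hit >= min_replicates
        if (any(ok)) unname(hit[which(ok)[1]]) else 0L
      },
      .groups = "drop"
    ) |>
    dplyr::rename(never_same_localization = "never_same")
}
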