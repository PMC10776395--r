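#' One-standard-error rule on a cross-validation curve
#'
#' Selects the most parsimonious regularization: the largest lambda whose
#' mean CV error does not exceed the minimum mean error plus the standard
#' error at the minimizer.
#'
#' @param lambda penalty values.
#' @param cvm mean cross-validation error per lambda.
#' @param cvsd standard error of the CV error per lambda.
#' @return the selected lambda.
#' @examples
#' select_lambda_1se(c(0.01, 0.1, 1), c(0.45, 0.50, 1.0), c(0.06, 0.05, 0.1))
#' @export
select_lambda_1se <- function(lambda, cvm, cvsd) {
  assert_that(length(lambda) == length(cvm) && length(cvm) == length(cvsd),
              "lambda, cvm, cvsd must have equal length")
  i_min <- which.min(cvm)
  threshold <- cvm[i_min] + cvsd[i_min]
  max(lambda[cvm <= threshold])
}

#' Elastic-net model with shared-fold alpha search and one-SE lambda
#'
#' Splits the data 80:20 into training and test sets, precomputes 10-fold CV
#' assignments on the training set (identical across the whole alpha grid,
#' so alpha values are compared on the same resamples), fits the elastic net
#' over alpha in {0, 0.1, ..., 1}, picks the alpha with the minimum mean CV
#' error, selects lambda by the one-standard-error rule, and evaluates on
#' the held-out 20% (area under the ROC curve for logistic models, mean
#' squared error for linear ones). Predictors are standardized internally by
#' the fitting routine; coefficients are returned on the original scale.
#'
#' @param x numeric predictor matrix (rows = observations).
#' @param y response (binary for `family = "binomial"`).
#' @param family "binomial" or "gaussian".
#' @param alpha_grid mixing values to scan.
#' @param nfolds CV folds (default 10).
#' @param train_share training share of the 80:20 split.
#' @param seed integer seed (split and folds).
#' @return a `gradloc_enet` list: `alpha`, `lambda`, `coefficients` (named,
#'   incl. intercept), `cv_curves` (tibble alpha, lambda, cvm, cvsd),
#'   `foldid`, `train_idx`, `test_metric` (named auc or mse), `family`.
#' @export
fit_penalized_model <- function(x, y, family = c("binomial", "gaussian"),
                                alpha_grid = seq(0, 1, by = 0.1),
                                nfolds = 10, train_share = 0.8, seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  assert_that(nrow(x) == length(y), "x and y sizes differ")
  if (length(unique(y)) < 2) {
    rlang::warn("constant response: returning an intercept-only fit")
    co <- stats::setNames(numeric(ncol(x) + 1),
                          c("(Intercept)", colnames(x)))
    co[1] <- if (family == "gaussian") mean(y) else qlogis(mean(y))
    return(structure(list(alpha = NA_real_, lambda = NA_real_,
                          coefficients = co, cv_curves = NULL, foldid = NULL,
                          train_idx = seq_along(y), test_metric = NULL,
                          family = family),
                     class = "gradloc_enet"))
  }
  sets <- with_seed(seed, {
    train_idx <- sort(sample(nrow(x), round(train_share * nrow(x))))
    foldid <- sample(rep_len(seq_len(nfolds), length(train_idx)))
    list(train_idx = train_idx, foldid = foldid)
  })
  train_idx <- sets$train_idx
  foldid <- sets$foldid
  xt <- x[train_idx, , drop = FALSE]
  yt <- y[train_idx]

  curves <- list()
  best <- list(cvm = Inf)
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(xt, yt, family = family, alpha = a,
                            foldid = foldid)
    curves[[length(curves) + 1]] <- tibble::tibble(
      alpha = a, lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
    if (min(cv$cvm) < best$cvm) {
      best <- list(cvm = min(cv$cvm), alpha = a, fit = cv)
    }
  }
  cv_curves <- dplyr::bind_rows(curves)
  lambda_sel <- select_lambda_1se(best$fit$lambda, best$fit$cvm,
                                  best$fit$cvsd)
  co <- as.matrix(coef(best$fit, s = lambda_sel))[, 1]

  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  metric <- NULL
  if (length(test_idx) > 0) {
    pred <- predict(best$fit, x[test_idx, , drop = FALSE], s = lambda_sel,
                    type = if (family == "binomial") "response" else "link")
    metric <- if (family == "binomial") {
      c(auc = as.numeric(pROC::auc(pROC::roc(y[test_idx], pred[, 1],
                                             quiet = TRUE,
                                             direction = "<"))))
    } else {
      c(mse = mean((y[test_idx] - pred[, 1])^2))
    }
  }
  structure(list(alpha = best$alpha, lambda = lambda_sel, coefficients = co,
                 cv_curves = cv_curves, foldid = foldid,
                 train_idx = train_idx, test_metric = metric,
                 family = family),
            class = "gradloc_enet")
}

#' @export
print.gradloc_enet <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf("<gradloc_enet> family %s, alpha = %s, lambda = %.4g, %d/%d nonzero coefficients\n",
              x$family, format(x$alpha), x$lambda, nz,
              length(x$coefficients) - 1))
  if (!is.null(x$test_metric)) {
    cat(sprintf("held-out %s = %.3f\n", names(x$test_metric), x$test_metric))
  }
  invisible(x)
}

#' Lasso of additive-model residuals on RBP binding
#'
#' Models the stress-resistant localization signal (residuals from
#' [fit_membrane_gam()]) as a function of binary RBP-binding columns with a
#' lasso (alpha = 1, one-SE lambda), separately for transcripts with and
#' without a signal peptide / transmembrane domain.
#'
#' @param residuals numeric GAM residuals.
#' @param rbp_columns binary matrix / data frame of RBP binding (same row
#'   order as `residuals`).
#' @param stratify_by_signal_peptide logical vector; TRUE = encodes a signal
#'   peptide or TM domain. NULL fits a single model.
#' @param seed integer seed.
#' @param min_group smallest group fitted (default 10).
#' @return named list of `gradloc_enet` fits (`with_sp_tm`, `without_sp_tm`
#'   or `all`), each with a `nonzero` tibble of selected RBPs and signs.
#' @export
model_residuals_by_rbp <- function(residuals, rbp_columns,
                                   stratify_by_signal_peptide = NULL,
                                   seed = 1L, min_group = 10) {
  xm <- as.matrix(rbp_columns)
  groups <- if (is.null(stratify_by_signal_peptide)) {
    list(all = rep(TRUE, length(residuals)))
  } else {
    list(with_sp_tm = stratify_by_signal_peptide,
         without_sp_tm = !stratify_by_signal_peptide)
  }
  out <- list()
  for (g in names(groups)) {
    idx <- which(groups[[g]])
    if (length(idx) < min_group) {
      rlang::warn(sprintf("group '%s' has fewer than %d members, skipped",
                          g, min_group))
      next
    }
    fit <- fit_penalized_model(xm[idx, , drop = FALSE], residuals[idx],
                               family = "gaussian", alpha_grid = 1,
                               seed = seed)
    co <- fit$coefficients[-1]
    fit$nonzero <- tibble::tibble(rbp = names(co)[co != 0],
                                  coefficient = unname(co[co != 0]))
    out[[g]] <- fit
  }
  out
}
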