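# Penalized region classifier with a permutation null.

#' Cross-validated region prediction with permutation null
#'
#' Trains a penalized multinomial logistic regression (via
#' [glmnet::cv.glmnet()]) to predict the cortical region of each cell from
#' its normalized log expression, with misclassification-error
#' cross-validation; performance is the best accuracy over the
#' regularization path. A null distribution is built by reshuffling the
#' region labels (sampling without replacement) and refitting; the one-tailed
#' p-value is the fraction of permuted accuracies at least as large as the
#' observed one.
#'
#' @param logcounts genes x cells matrix of normalized log expression.
#' @param regions region label per cell (>= 2 distinct values).
#' @param nfolds cross-validation folds (default 20).
#' @param n_permutations label shuffles for the null (default 1000).
#' @param alpha elastic-net mixing parameter passed to glmnet: 0 = ridge
#'   (default), 1 = lasso.
#' @param seed optional integer seed (controls fold assignment and
#'   shuffles).
#' @return an object of class `region_cv`: list with `accuracy`,
#'   `null_accuracies`, `p_value`, `n_cells`, `regions`.
#' @export
region_prediction_cv <- function(logcounts, regions, nfolds = 20,
                                 n_permutations = 1000, alpha = 0,
                                 seed = NULL) {
  x <- t(as.matrix(logcounts))  # cells x genes for glmnet
  y <- factor(regions)
  if (nlevels(y) < 2) abort("Need at least 2 regions.")
  if (nrow(x) < nfolds) abort("Need at least as many cells as folds.")
  if (min(table(y)) < 2) abort("Every region needs at least 2 cells.")
  check_count(n_permutations, "n_permutations", min = 0)
  if (!is.null(seed)) set.seed(seed)

  cv_accuracy <- function(labels) {
    fit <- glmnet::cv.glmnet(x, labels, family = "multinomial",
                             type.measure = "class", nfolds = nfolds,
                             alpha = alpha)
    1 - min(fit$cvm)
  }
  accuracy <- cv_accuracy(y)
  null_acc <- if (n_permutations > 0) {
    vapply(seq_len(n_permutations),
           function(i) cv_accuracy(sample(y)), numeric(1))
  } else {
    numeric(0)
  }
  p_value <- if (length(null_acc) > 0) mean(null_acc >= accuracy) else NA_real_
  structure(
    list(accuracy = accuracy, null_accuracies = null_acc, p_value = p_value,
         n_cells = nrow(x), regions = levels(y),
         n_permutations = n_permutations),
    class = "region_cv"
  )
}

#' @export
print.region_cv <- function(x, ...) {
  cat("Cross-validated region prediction\n")
  cat(sprintf("  accuracy %.3f over %d cells (%s)\n",
              x$accuracy, x$n_cells, paste(x$regions, collapse = " vs ")))
  if (length(x$null_accuracies) > 0) {
    cat(sprintf("  permutation null: mean %.3f, p = %.4g (%d shuffles)\n",
                mean(x$null_accuracies), x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' @export
glance.region_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         null_mean = if (length(x$null_accuracies)) mean(x$null_accuracies) else NA_real_,
         p_value = x$p_value, n_cells = x$n_cells,
         n_permutations = x$n_permutations)
}
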