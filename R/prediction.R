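# Per-property kernel SVMs: class-bias filtering, C selection on training
# accuracy, fold-based reliability scores, micro-averaged metrics and the
# exact sign test for method comparison.

#' Cross-validation configuration
#'
#' @param folds Number of folds (>= 2).
#' @param C_grid Candidate soft-margin parameters; the smallest value
#'   achieving the best training accuracy is selected.
#' @param seed Seed for the fold shuffle (recorded in outputs).
#' @param bias_threshold Class-bias threshold for [class_bias_filter()].
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 5, C_grid = 2^(-3:7), seed = 1,
                      bias_threshold = 0.9) {
  stopifnot(folds >= 2, length(C_grid) >= 1, all(C_grid > 0),
            bias_threshold > 0.5, bias_threshold <= 1)
  structure(list(folds = as.integer(folds), C_grid = as.numeric(C_grid),
                 seed = as.integer(seed), bias_threshold = bias_threshold),
            class = "cv_config")
}

#' Fold assignment by compound
#'
#' One shuffled assignment shared across all properties and kernels, so every
#' method sees identical training and testing compounds.
#'
#' @param n Number of compounds.
#' @param folds Number of folds.
#' @param seed Shuffle seed.
#' @return Integer vector of fold labels in `1..folds`.
#' @export
make_folds <- function(n, folds = 5, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Filter fingerprint properties by class bias
#'
#' Keeps properties whose majority-class fraction is strictly below the
#' threshold; heavily biased properties are trivially predicted by the
#' majority class and carry no signal for retrieval.
#'
#' @param Y Matrix in \{-1, +1\} (rows compounds, columns properties).
#' @param threshold Bias threshold in (0.5, 1].
#' @return The column-subset of `Y` (possibly zero columns).
#' @export
class_bias_filter <- function(Y, threshold = 0.9) {
  stopifnot(threshold > 0.5, threshold <= 1)
  bias <- apply(Y, 2, function(y) max(mean(y == 1), mean(y == -1)))
  Y[, bias < threshold, drop = FALSE]
}

# ksvm on a precomputed kernel; returns NULL when the fit is impossible
.ksvm_fit <- function(K, y, C) {
  yf <- factor(y, levels = c(-1, 1))
  tryCatch(
    # shrinking off: the heuristic costs more than it saves at cohort sizes
    # in the low hundreds and the solution is unchanged
    kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, C = C, kernel = "matrix",
                  shrinking = FALSE),
    error = function(e) NULL)
}

.ksvm_predict <- function(fit, K_cross) {
  sv <- kernlab::SVindex(fit)
  pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(K_cross[, sv, drop = FALSE]))
  as.numeric(as.character(pred))
}

.ksvm_decision <- function(fit, K_cross) {
  sv <- kernlab::SVindex(fit)
  d <- kernlab::predict(fit, kernlab::as.kernelMatrix(K_cross[, sv, drop = FALSE]),
                        type = "decision")
  as.numeric(d)
}

#' Train one fingerprint-property SVM
#'
#' Fits a soft-margin SVM on the precomputed kernel for every `C` in the
#' grid, selects the smallest `C` with the best training accuracy, refits on
#' the full data, and estimates the property's reliability as the
#' out-of-fold accuracy under `cfg$folds`-fold cross-validation within the
#' training set (so test compounds never leak into reliabilities).
#'
#' @param K PSD kernel matrix over the training compounds (dimnames = ids).
#' @param y Label vector in \{-1, +1\} with both classes present.
#' @param cfg A [cv_config()].
#' @param property Property name used in messages.
#' @param reliability Estimate the out-of-fold reliability (set `FALSE` to
#'   skip the inner cross-validation when only predictions are needed).
#' @return An object of class `property_model` with elements `fit`, `C`,
#'   `reliability`, `ids`, `property`.
#' @export
train_property <- function(K, y, cfg = cv_config(), property = "property",
                           reliability = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(K) == n, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2)
    stop("property '", property, "' has a single class; cannot train")
  acc <- vapply(cfg$C_grid, function(C) {
    fit <- .ksvm_fit(K, y, C)
    if (is.null(fit)) return(NA_real_)
    mean(.ksvm_predict(fit, K) == y)
  }, numeric(1))
  if (all(is.na(acc))) stop("SVM training failed for property '", property, "'")
  best <- which(acc == max(acc, na.rm = TRUE))[1]  # smallest C wins ties
  C <- cfg$C_grid[best]
  rel <- NA_real_
  if (isTRUE(reliability)) {
    fold <- make_folds(n, cfg$folds, cfg$seed)
    oof <- rep(NA_real_, n)
    for (f in seq_len(cfg$folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) {
        oof[!tr] <- as.numeric(names(which.max(table(y[tr]))))
        next
      }
      fit_f <- .ksvm_fit(K[tr, tr, drop = FALSE], y[tr], C)
      oof[!tr] <- if (is.null(fit_f))
        as.numeric(names(which.max(table(y[tr]))))
      else .ksvm_predict(fit_f, K[!tr, tr, drop = FALSE])
    }
    rel <- mean(oof == y)
  }
  fit <- .ksvm_fit(K, y, C)
  structure(list(fit = fit, C = C, reliability = rel,
                 ids = rownames(K), property = property,
                 train_accuracy = max(acc, na.rm = TRUE),
                 folds_seed = cfg$seed),
            class = "property_model")
}

#' @export
print.property_model <- function(x, ...) {
  cat(sprintf("Property SVM '%s': C = %g, training accuracy %.3f, reliability %.3f\n",
              x$property, x$C, x$train_accuracy, x$reliability))
  invisible(x)
}

#' Predict fingerprints for new compounds
#'
#' @param models List of `property_model` objects sharing one training set.
#' @param K_cross Cross-kernel matrix (rows = test compounds, columns =
#'   training compounds in the models' id order), computed with the same
#'   kernel and weights as training.
#' @return List with `fingerprints` (matrix in \{-1, +1\}) and `margins`
#'   (decision values).
#' @export
predict_fingerprints <- function(models, K_cross) {
  ids <- models[[1]]$ids
  for (m in models)
    if (!identical(m$ids, ids))
      stop("models disagree on the training compound ordering")
  if (!is.null(colnames(K_cross)) && !is.null(ids) &&
      !identical(colnames(K_cross), ids))
    stop("cross-kernel columns do not match the training ids")
  nt <- nrow(K_cross)
  m <- length(models)
  Yp <- matrix(NA_real_, nt, m)
  Mg <- matrix(NA_real_, nt, m)
  for (j in seq_len(m)) {
    fit <- models[[j]]$fit
    Yp[, j] <- .ksvm_predict(fit, K_cross)
    Mg[, j] <- .ksvm_decision(fit, K_cross)
  }
  colnames(Yp) <- colnames(Mg) <- vapply(models, `[[`, character(1), "property")
  rownames(Yp) <- rownames(Mg) <- rownames(K_cross)
  list(fingerprints = Yp, margins = Mg)
}

#' Micro-averaged accuracy and F1
#'
#' Pools all compound-by-property cells: accuracy is the fraction of
#' agreeing entries; F1 is `2TP / (2TP + FP + FN)` with `+1` as the positive
#' class. Both are returned in percent.
#'
#' @param Y_true,Y_pred Matrices in \{-1, +1\} of equal shape.
#' @return Named numeric vector `c(accuracy, F1)` in percent.
#' @export
micro_metrics <- function(Y_true, Y_pred) {
  if (!all(dim(Y_true) == dim(Y_pred))) stop("shape mismatch")
  acc <- mean(Y_true == Y_pred) * 100
  tp <- sum(Y_true == 1 & Y_pred == 1)
  fp <- sum(Y_true == -1 & Y_pred == 1)
  fn <- sum(Y_true == 1 & Y_pred == -1)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn) * 100
  c(accuracy = acc, F1 = f1)
}

#' Exact sign test between two methods
#'
#' Pairs per-property scores, drops ties, and returns the one-sided exact
#' binomial p-value for the number of wins of method A under a fair coin.
#'
#' @param scores_a,scores_b Paired per-property score vectors.
#' @return List with `n_wins`, `n_losses`, `p_value` (`NA` and
#'   `undefined = TRUE` when every pair is tied).
#' @export
sign_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  wins <- sum(scores_a > scores_b)
  losses <- sum(scores_b > scores_a)
  n <- wins + losses
  if (n == 0)
    return(list(n_wins = 0L, n_losses = 0L, p_value = NA_real_,
                undefined = TRUE))
  p <- stats::binom.test(wins, n, p = 0.5, alternative = "greater")$p.value
  list(n_wins = wins, n_losses = losses, p_value = p, undefined = FALSE)
}
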