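# The core estimator: an MKL-weighted bank of per-property kernel SVMs that
# maps MS/MS kernels to molecular fingerprints, with reliabilities for
# downstream Poisson-binomial retrieval.

#' Fit the kernel fingerprint predictor
#'
#' Combines a bundle of kernels with the requested multiple-kernel-learning
#' method and trains one soft-margin SVM per fingerprint property on the
#' combined kernel. `unimkl`, `align` and `alignf` learn one shared weight
#' vector (target kernel `YY'`); `qcmkl` and `lp` depend on the SVM and are
#' fit per property.
#'
#' @param kernels Named list of symmetric PSD kernel matrices over the
#'   training compounds (shared dimnames = compound ids).
#' @param Y Fingerprint matrix in \{-1, +1\} (rows compounds, columns named
#'   properties).
#' @param method One of `"unimkl"`, `"align"`, `"alignf"`, `"qcmkl"`,
#'   `"lp"`.
#' @param p Norm order for `method = "lp"`.
#' @param svm_C Soft-margin parameter for the MKL inner SVMs.
#' @param cv A [cv_config()]: C grid and folds for the per-property SVMs and
#'   reliabilities, and the class-bias threshold.
#' @param normalize Cosine-normalize the kernels before MKL (recommended:
#'   alignment and weight scales are otherwise dominated by kernel
#'   magnitude).
#' @param bias_filter Drop properties with class bias at or above
#'   `cv$bias_threshold` before training.
#' @param reliability Estimate per-property reliabilities by inner
#'   cross-validation (needed for retrieval; skip for speed when only
#'   predictions are wanted).
#' @return An object of class `fingerid`.
#' @seealso [predict.fingerid()], [rank_candidates()]
#' @export
fingerid <- function(kernels, Y, method = c("unimkl", "align", "alignf",
                                            "qcmkl", "lp"),
                     p = 2, svm_C = 1, cv = cv_config(), normalize = TRUE,
                     bias_filter = TRUE, reliability = TRUE) {
  method <- match.arg(method)
  .check_bundle(kernels)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(kernels[[1]]))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("prop_%02d", seq_len(ncol(Y)))
  train_diag <- lapply(kernels, diag)
  if (normalize) kernels <- lapply(kernels, .safe_cosine)
  if (bias_filter) Y <- class_bias_filter(Y, cv$bias_threshold)
  if (!ncol(Y)) stop("no properties survive the class-bias filter")
  m <- ncol(Y)
  shared <- method %in% c("unimkl", "align", "alignf")
  if (shared) {
    w <- switch(method,
                unimkl = unimkl(kernels),
                align = align_weights(kernels, Y),
                alignf = alignf(kernels, Y))
    Kmu <- combine_kernels(kernels, w)
    mu <- w$mu
  } else {
    q <- length(kernels)
    mu <- matrix(NA_real_, if (method == "qcmkl") q * (q + 1) / 2 else q, m)
  }
  models <- vector("list", m)
  weights <- vector("list", m)
  for (j in seq_len(m)) {
    y <- Y[, j]
    if (!shared) {
      wj <- if (method == "qcmkl") qcmkl(kernels, y, svm_C = svm_C)
            else lp_mkl(kernels, y, p = p, svm_C = svm_C)
      weights[[j]] <- wj
      mu[, j] <- wj$mu
      Kj <- if (method == "qcmkl") combine_kernels(qcmkl_expand(kernels), wj)
            else combine_kernels(kernels, wj)
    } else Kj <- Kmu
    models[[j]] <- tryCatch(
      train_property(Kj, y, cv, property = colnames(Y)[j],
                     reliability = reliability),
      error = function(e) .constant_model(y, rownames(kernels[[1]]),
                                          colnames(Y)[j]))
  }
  structure(list(method = method, p = if (method == "lp") p else NULL,
                 svm_C = svm_C, mu = mu,
                 kernel_names = names(kernels),
                 mkl = if (shared) w else weights,
                 models = models,
                 reliabilities = vapply(models, `[[`, numeric(1), "reliability"),
                 properties = colnames(Y),
                 ids = rownames(kernels[[1]]),
                 n = nrow(Y), normalize = normalize,
                 train_diag = train_diag, cv = cv,
                 call = match.call()),
            class = "fingerid")
}

# majority-class fallback used when a property cannot support an SVM inside
# a training fold (e.g. one class only)
.constant_model <- function(y, ids, property) {
  maj <- as.numeric(names(which.max(table(y))))
  structure(list(fit = NULL, majority = maj, C = NA_real_,
                 reliability = mean(y == maj), ids = ids,
                 property = property, train_accuracy = mean(y == maj)),
            class = "property_model")
}

#' @export
print.fingerid <- function(x, ...) {
  cat(sprintf("Kernel fingerprint predictor (%s): %d kernels, %d properties, %d compounds\n",
              x$method, length(x$kernel_names), length(x$properties), x$n))
  cat(sprintf("mean reliability: %.3f\n", mean(x$reliabilities)))
  invisible(x)
}

#' @export
summary.fingerid <- function(object, ...) {
  cat(sprintf("Kernel fingerprint predictor — method %s\n", object$method))
  cat(sprintf("compounds: %d   properties: %d   kernels: %s\n", object$n,
              length(object$properties),
              paste(object$kernel_names, collapse = ", ")))
  if (is.matrix(object$mu)) {
    cat("per-property kernel weights (column means):\n")
    print(round(rowMeans(object$mu), 4))
  } else {
    mu <- stats::setNames(object$mu, object$kernel_names)
    cat("shared kernel weights:\n")
    print(round(mu, 4))
  }
  cat("reliability quartiles:\n")
  print(round(stats::quantile(object$reliabilities), 3))
  invisible(object)
}

#' @export
coef.fingerid <- function(object, ...) {
  if (is.matrix(object$mu)) object$mu
  else stats::setNames(object$mu, object$kernel_names)
}

#' Predict fingerprints for new compounds
#'
#' @param object A fitted [fingerid()] model.
#' @param newkernels Named list of cross-kernel matrices (rows = test
#'   compounds, columns = training compounds) for the same kernels, in the
#'   same order, as used at fit time. Supply *unnormalized* values when the
#'   model was fit with `normalize = TRUE` and pass `test_diag`.
#' @param test_diag Named list of self-similarity vectors `K(t,t)` of the
#'   test compounds per kernel; required when the model normalizes.
#' @param ... Unused.
#' @return List with `fingerprints` (\{-1, +1\} matrix), `margins`, and the
#'   model `reliabilities`.
#' @export
predict.fingerid <- function(object, newkernels, test_diag = NULL, ...) {
  stopifnot(identical(names(newkernels), object$kernel_names))
  if (object$normalize) {
    if (is.null(test_diag))
      stop("model was fit with normalize = TRUE; supply test_diag")
    newkernels <- Map(function(K, td, trd) {
      st <- ifelse(td > 0, 1 / sqrt(td), 0)
      sr <- ifelse(trd > 0, 1 / sqrt(trd), 0)
      K * outer(st, sr)
    }, newkernels, test_diag, object$train_diag)
  }
  shared <- object$method %in% c("unimkl", "align", "alignf")
  preds <- matrix(NA_real_, nrow(newkernels[[1]]), length(object$properties))
  margs <- preds
  if (shared) {
    Kc <- combine_kernels(newkernels, object$mu)
    out <- .predict_models(object$models, Kc)
    preds <- out$fingerprints; margs <- out$margins
  } else {
    base <- if (object$method == "qcmkl") qcmkl_expand(newkernels) else newkernels
    for (j in seq_along(object$properties)) {
      Kc <- combine_kernels(base, object$mu[, j])
      out <- .predict_models(object$models[j], Kc)
      preds[, j] <- out$fingerprints; margs[, j] <- out$margins
    }
  }
  colnames(preds) <- colnames(margs) <- object$properties
  rownames(preds) <- rownames(margs) <- rownames(newkernels[[1]])
  list(fingerprints = preds, margins = margs,
       reliabilities = object$reliabilities)
}

.predict_models <- function(models, K_cross) {
  nt <- nrow(K_cross)
  m <- length(models)
  Yp <- matrix(NA_real_, nt, m); Mg <- matrix(NA_real_, nt, m)
  for (j in seq_len(m)) {
    mod <- models[[j]]
    if (is.null(mod$fit)) {
      Yp[, j] <- mod$majority; Mg[, j] <- mod$majority
    } else {
      Yp[, j] <- .ksvm_predict(mod$fit, K_cross)
      Mg[, j] <- .ksvm_decision(mod$fit, K_cross)
    }
  }
  list(fingerprints = Yp, margins = Mg)
}

#' Cross-validated fingerprint prediction
#'
#' The evaluation protocol: one fold assignment by compound shared across
#' all properties and kernels; per fold the model is fit on the training
#' block and predicts the held-out block; metrics pool the out-of-fold
#' predictions.
#'
#' @inheritParams fingerid
#' @return List with `micro` (accuracy/F1 in percent), `per_property`
#'   out-of-fold accuracy vector, `predictions`, the filtered `Y`, and the
#'   fold assignment.
#' @export
fingerid_cv <- function(kernels, Y, method = "unimkl", p = 2, svm_C = 1,
                        cv = cv_config(), normalize = TRUE) {
  .check_bundle(kernels)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("prop_%02d", seq_len(ncol(Y)))
  if (normalize) kernels <- lapply(kernels, .safe_cosine)
  Y <- class_bias_filter(Y, cv$bias_threshold)
  if (!ncol(Y)) stop("no properties survive the class-bias filter")
  n <- nrow(Y)
  fold <- make_folds(n, cv$folds, cv$seed)
  pred <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  for (f in seq_len(cv$folds)) {
    tr <- fold != f
    Ktr <- lapply(kernels, function(K) K[tr, tr, drop = FALSE])
    Kcr <- lapply(kernels, function(K) K[!tr, tr, drop = FALSE])
    fit <- fingerid(Ktr, Y[tr, , drop = FALSE], method = method, p = p,
                    svm_C = svm_C, cv = cv, normalize = FALSE,
                    bias_filter = FALSE, reliability = FALSE)
    pred[!tr, ] <- predict(fit, Kcr)$fingerprints
  }
  list(micro = micro_metrics(Y, pred),
       per_property = colMeans(Y == pred) * 100,
       predictions = pred, Y = Y, fold = fold)
}
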