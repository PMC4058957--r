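# Multiple kernel learning: uniform weights, centered-alignment weights
# (independent and jointly maximized), quadratic-combination MKL over the
# Hadamard-expanded bundle, and lp-norm MKL via the alternating wrapper.

#' Double-center a kernel matrix
#'
#' `K_c = (I - ee'/n) K (I - ee'/n)`; row and column sums of the result are
#' zero and centering is idempotent.
#'
#' @param K Square kernel matrix.
#' @return The centered matrix.
#' @export
center_kernel <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("center_kernel needs a square matrix")
  rm_ <- rowMeans(K); cm <- colMeans(K); mm <- mean(K)
  K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + mm
}

#' Centered kernel alignment
#'
#' Cosine similarity of two kernel matrices under the Frobenius inner
#' product after double-centering; lies in \[0, 1\] for PSD inputs.
#'
#' @param K1,K2 Square kernel matrices of equal size.
#' @return The alignment value.
#' @export
centered_alignment <- function(K1, K2) {
  A <- center_kernel(K1); B <- center_kernel(K2)
  na <- sqrt(sum(A * A)); nb <- sqrt(sum(B * B))
  if (na == 0 || nb == 0) stop("degenerate kernel: zero centered Frobenius norm")
  sum(A * B) / (na * nb)
}

.target_kernel <- function(y) {
  if (is.matrix(y)) tcrossprod(y) else tcrossprod(as.numeric(y))
}

.check_bundle <- function(kernels) {
  if (!length(kernels)) stop("empty kernel bundle")
  n <- nrow(kernels[[1]])
  ok <- vapply(kernels, function(K) is.matrix(K) && all(dim(K) == n), logical(1))
  if (!all(ok)) stop("kernel bundle matrices must share one size/ordering")
  invisible(n)
}

.mkl_weights <- function(mu, method, kernel_ids = NULL, diagnostics = list()) {
  structure(list(mu = as.numeric(mu), method = method,
                 kernel_ids = kernel_ids, diagnostics = diagnostics),
            class = "mkl_weights")
}

#' @export
print.mkl_weights <- function(x, ...) {
  cat("MKL weights (", x$method, "):\n", sep = "")
  mu <- x$mu
  names(mu) <- if (!is.null(x$kernel_ids)) x$kernel_ids else seq_along(mu)
  print(round(mu, 4))
  if (!is.null(x$diagnostics$iterations))
    cat("iterations:", x$diagnostics$iterations, "\n")
  invisible(x)
}

#' Combine a kernel bundle with weights
#'
#' @param kernels Named list of kernel matrices.
#' @param w An `mkl_weights` object or a numeric weight vector.
#' @return The weighted sum of the matrices.
#' @export
combine_kernels <- function(kernels, w) {
  mu <- if (inherits(w, "mkl_weights")) w$mu else as.numeric(w)
  stopifnot(length(mu) == length(kernels))
  Reduce(`+`, Map(function(K, m) m * K, kernels, mu))
}

#' Uniform kernel combination (UNIMKL)
#'
#' @param kernels Named list of kernel matrices.
#' @return `mkl_weights` with equal weights summing to one.
#' @export
unimkl <- function(kernels) {
  q <- length(kernels)
  if (!q) stop("empty kernel bundle")
  .mkl_weights(rep(1 / q, q), "unimkl", names(kernels))
}

#' Independent centered-alignment weights (ALIGN)
#'
#' Each kernel is weighted by its centered alignment with the target kernel
#' `yy'` (single label) or `YY'` (label matrix), i.e.
#' `mu_k` proportional to `<K_kc, K_Yc>_F / ||K_kc||_F`, scaled to sum one.
#'
#' @param kernels Named list of kernel matrices.
#' @param y Label vector in \{-1, +1\} or a label matrix `Y`.
#' @return `mkl_weights` with non-negative weights summing to one.
#' @export
align_weights <- function(kernels, y) {
  .check_bundle(kernels)
  KYc <- center_kernel(.target_kernel(y))
  raw <- vapply(kernels, function(K) {
    Kc <- center_kernel(K)
    nk <- sqrt(sum(Kc * Kc))
    if (nk == 0) stop("degenerate kernel: zero centered Frobenius norm")
    sum(Kc * KYc) / nk
  }, numeric(1))
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) stop("all kernels have non-positive alignment with the target")
  .mkl_weights(raw / sum(raw), "align", names(kernels),
               diagnostics = list(alignments = raw))
}

# <K_ic, K_jc>_F matrix and <K_ic, K_Yc>_F vector, the sufficient statistics
# of centered-alignment optimization
.alignment_stats <- function(kernels, y) {
  KYc <- center_kernel(.target_kernel(y))
  Kc <- lapply(kernels, center_kernel)
  q <- length(Kc)
  M <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in i:q)
    M[i, j] <- M[j, i] <- sum(Kc[[i]] * Kc[[j]])
  a <- vapply(Kc, function(K) sum(K * KYc), numeric(1))
  list(M = M, a = a, y_norm = sqrt(sum(KYc * KYc)))
}

#' Alignment maximization weights (ALIGNF)
#'
#' Jointly maximizes the centered alignment of the combined kernel with the
#' target kernel over the non-negative part of the unit sphere. Solved as
#' the equivalent non-negative least-squares problem
#' `min_v v'Mv - 2 v'a, v >= 0` with `M_kl = <K_kc, K_lc>_F` and
#' `a_k = <K_kc, K_Yc>_F`, then `mu = v / ||v||_2`.
#'
#' @inheritParams align_weights
#' @return `mkl_weights` with `||mu||_2 = 1`; diagnostics carry the achieved
#'   alignment objective.
#' @export
alignf <- function(kernels, y) {
  .check_bundle(kernels)
  st <- .alignment_stats(kernels, y)
  q <- length(kernels)
  if (q == 1L) {
    obj <- st$a / sqrt(st$M[1, 1]) / st$y_norm
    return(.mkl_weights(1, "alignf", names(kernels),
                        diagnostics = list(objective = as.numeric(obj))))
  }
  # factor M = S'S (eigen square root with a tiny ridge), then the QP is
  # min ||S v - d||^2 with S' d = a
  M <- st$M + diag(1e-10 * max(diag(st$M)), q)
  es <- eigen(M, symmetric = TRUE)
  lam <- pmax(es$values, 1e-12 * max(es$values))
  S <- diag(sqrt(lam)) %*% t(es$vectors)
  d <- as.numeric(diag(1 / sqrt(lam), q) %*% t(es$vectors) %*% st$a)
  v <- pracma::lsqnonneg(S, d)$x
  if (all(v <= 0)) stop("degenerate ALIGNF instance: zero solution")
  mu <- v / sqrt(sum(v^2))
  obj <- sum(mu * st$a) / sqrt(drop(t(mu) %*% st$M %*% mu)) / st$y_norm
  .mkl_weights(mu, "alignf", names(kernels),
               diagnostics = list(objective = obj))
}

#' Hadamard expansion of a kernel bundle
#'
#' Returns the `q(q+1)/2` kernels `K_i * K_j` (entrywise) for `i < j`
#' together with the originals `K_i` (the `i = j` case); every expanded
#' kernel is PSD by the Schur product theorem.
#'
#' @param kernels Named list of kernel matrices.
#' @return Named list of `q(q+1)/2` matrices.
#' @export
qcmkl_expand <- function(kernels) {
  .check_bundle(kernels)
  q <- length(kernels)
  nms <- names(kernels)
  if (is.null(nms)) nms <- paste0("K", seq_len(q))
  out <- list()
  for (i in seq_len(q)) for (j in i:q) {
    out[[paste0(nms[i], if (i != j) paste0("*", nms[j]) else "")]] <-
      if (i == j) kernels[[i]] else kernels[[i]] * kernels[[j]]
  }
  out
}

# Soft-margin SVM dual on a precomputed kernel, solved by interior point
# (kernlab::ipop) and polished on the KKT system of the free set so the
# objective is accurate to near machine precision.  Returns the dual vector
# alpha, the signed coefficients c = y * alpha and the dual objective.
.svm_dual <- function(K, y, C, ridge = 1e-10) {
  n <- length(y)
  stopifnot(nrow(K) == n)
  G <- K * outer(y, y)
  Gr <- G + diag(ridge, n)
  sol <- kernlab::ipop(c = matrix(-1, n, 1), H = Gr,
                       A = matrix(y, 1, n), b = 0, r = 0,
                       l = matrix(0, n, 1), u = matrix(C, n, 1),
                       sigf = 9, maxiter = 200)
  a <- as.numeric(kernlab::primal(sol))
  a <- pmin(pmax(a, 0), C)
  # KKT polish: solve the equality-constrained system on the free set
  for (pass in 1:3) {
    eps <- C * 1e-6
    free <- which(a > eps & a < C - eps)
    atC <- which(a >= C - eps)
    if (length(free) >= 1) {
      rhs <- rep(1, length(free)) -
        if (length(atC)) as.numeric(Gr[free, atC, drop = FALSE] %*% rep(C, length(atC))) else 0
      A_ <- rbind(cbind(Gr[free, free, drop = FALSE], y[free]),
                  c(y[free], 0))
      b_ <- c(rhs, -sum(y[atC]) * C)
      sol2 <- tryCatch(solve(A_, b_), error = function(e) NULL)
      if (is.null(sol2)) break
      af <- sol2[seq_along(free)]
      if (any(af < -eps) || any(af > C + eps)) {
        af <- pmin(pmax(af, 0), C)
        a[free] <- af; a[atC] <- C; a[setdiff(seq_len(n), c(free, atC))] <- 0
        next
      }
      a[free] <- pmin(pmax(af, 0), C)
      a[atC] <- C
      a[setdiff(seq_len(n), c(free, atC))] <- 0
      break
    } else break
  }
  obj <- sum(a) - 0.5 * drop(t(a) %*% Gr %*% a)
  list(alpha = a, coef = a * y, objective = obj)
}

# lp-norm closed-form weight update: mu_k = ||w_k||^{2/(p+1)} normalized so
# that ||mu||_p = 1; p = 1 gives the simplex (sum-to-one) update.
.lp_update <- function(wnorm2, p) {
  wk <- sqrt(pmax(wnorm2, 0))
  if (all(wk == 0)) return(NULL)
  num <- wk^(2 / (p + 1))
  den <- sum(wk^(2 * p / (p + 1)))^(1 / p)
  num / den
}

.mkl_wrapper <- function(kernels, y, p, svm_C, tol, max_iter, method) {
  n <- .check_bundle(kernels)
  y <- as.numeric(y)
  stopifnot(length(y) == n, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  q <- length(kernels)
  mu <- rep(q^(-1 / p), q)
  trace <- numeric()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Kmu <- combine_kernels(kernels, mu)
    fit <- .svm_dual(Kmu, y, svm_C)
    trace <- c(trace, fit$objective)
    cf <- fit$coef
    wnorm2 <- mu^2 * vapply(kernels, function(K) drop(t(cf) %*% K %*% cf),
                            numeric(1))
    mu_new <- .lp_update(wnorm2, p)
    if (is.null(mu_new)) break  # zero margin vector: keep current weights
    delta <- if (length(trace) > 1)
      abs(trace[iter] - trace[iter - 1]) / max(abs(trace[iter]), 1e-12)
    else Inf
    mu <- mu_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop("MKL wrapper did not converge in ", max_iter,
           " iterations; objective trace: ",
           paste(signif(utils::tail(trace, 5), 6), collapse = ", "))
  }
  .mkl_weights(mu, method, names(kernels),
               diagnostics = list(objective_trace = trace, iterations = iter))
}

#' lp-norm multiple kernel learning
#'
#' Alternating wrapper: solve the soft-margin SVM dual on the combined
#' kernel, compute `||w_k||^2 = mu_k^2 alpha' G(K_k) alpha` with
#' `G(K) = diag(y) K diag(y)`, then apply the closed-form lp-norm update
#' `mu_k = ||w_k||^{2/(p+1)} / (sum_k ||w_k||^{2p/(p+1)})^{1/p}`, which keeps
#' `||mu||_p = 1`. Iterates until the relative objective change falls below
#' `tol`.
#'
#' @param kernels Named list of PSD kernel matrices.
#' @param y Label vector in \{-1, +1\}.
#' @param p Norm order (> 1; use [qcmkl()] for the simplex-constrained case).
#' @param svm_C Soft-margin parameter.
#' @param tol Relative objective-change stopping tolerance.
#' @param max_iter Maximum wrapper iterations (error when exceeded).
#' @return `mkl_weights` with the objective trace in diagnostics.
#' @export
lp_mkl <- function(kernels, y, p = 2, svm_C = 1, tol = 1e-4, max_iter = 100) {
  stopifnot(p > 1)
  .mkl_wrapper(kernels, y, p, svm_C, tol, max_iter, paste0("l", p, "-mkl"))
}

#' Quadratic-combination MKL (QCMKL)
#'
#' Expands the bundle with all pairwise Hadamard products ([qcmkl_expand()])
#' and learns convex weights (`mu >= 0`, sum one) over the expanded set by
#' the alternating wrapper with the simplex (`p = 1`) update — an
#' optimization route equivalent to the semidefinite-programming
#' formulation of the same soft-margin objective.
#'
#' @inheritParams lp_mkl
#' @return `mkl_weights` over the expanded bundle (length `q(q+1)/2`).
#' @export
qcmkl <- function(kernels, y, svm_C = 1, tol = 1e-4, max_iter = 100) {
  expanded <- qcmkl_expand(kernels)
  .mkl_wrapper(expanded, y, 1, svm_C, tol, max_iter, "qcmkl")
}
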