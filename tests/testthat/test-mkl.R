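rand_psd <- function(n, r = 3) {
  X <- matrix(rnorm(n * r), n)
  tcrossprod(X)
}

test_that("centering zeroes row sums, kills constants and is idempotent", {
  set.seed(1)
  K <- rand_psd(5)
  Kc <- center_kernel(K)
  expect_lt(max(abs(rowSums(Kc))), 1e-10)
  expect_lt(max(abs(colSums(Kc))), 1e-10)
  expect_equal(center_kernel(Kc), Kc, tolerance = 1e-12)
  e <- matrix(1, 4, 4)
  expect_equal(center_kernel(e), matrix(0, 4, 4))
  expect_error(center_kernel(matrix(1, 2, 3)), "square")
})

test_that("centered alignment is one on self, scale-free and in [0,1] for PSD", {
  set.seed(2)
  K <- rand_psd(8)
  expect_equal(centered_alignment(K, K), 1)
  expect_equal(centered_alignment(K, 3.7 * K), 1)
  for (i in 1:10) {
    A <- rand_psd(8); B <- rand_psd(8)
    r <- centered_alignment(A, B)
    expect_gte(r, 0); expect_lte(r, 1)
    # matches the direct Frobenius formula
    Ac <- center_kernel(A); Bc <- center_kernel(B)
    expect_equal(r, sum(Ac * Bc) / sqrt(sum(Ac^2) * sum(Bc^2)))
  }
  expect_error(centered_alignment(matrix(1, 4, 4), K), "degenerate")
})

test_that("uniform weights are 1/q and combine to the arithmetic mean", {
  ks <- lapply(1:4, function(i) rand_psd(6))
  w <- unimkl(ks)
  expect_equal(w$mu, rep(0.25, 4))
  expect_equal(combine_kernels(ks, w), Reduce(`+`, ks) / 4)
  expect_equal(unimkl(ks[1])$mu, 1)
  expect_error(unimkl(list()), "empty")
})

test_that("ALIGN weights favor the target-aligned kernel and permute with the bundle", {
  set.seed(3)
  n <- 14
  y <- sample(c(-1, 1), n, replace = TRUE)
  KY <- tcrossprod(y)
  Krand <- rand_psd(n)
  w <- align_weights(list(target = KY, noise = Krand), y)
  expect_gt(w$mu[1], w$mu[2])
  expect_equal(sum(w$mu), 1)
  # identical kernels: uniform
  w2 <- align_weights(list(a = Krand, b = Krand, c = Krand), y)
  expect_equal(w2$mu, rep(1 / 3, 3))
  # permuting the bundle permutes the weights
  w3 <- align_weights(list(noise = Krand, target = KY), y)
  expect_equal(w3$mu, w$mu[2:1])
})

test_that("ALIGNF solves the alignment maximization on the unit quadrant", {
  set.seed(4)
  n <- 16
  y <- sample(c(-1, 1), n, replace = TRUE)
  # one perfectly aligned kernel + one (centered-)orthogonal pure-noise
  # direction: the aligned kernel takes all the weight
  KY <- tcrossprod(y)
  z <- rnorm(n)
  z <- resid(lm(z ~ y))           # orthogonal to the label direction
  Kz <- tcrossprod(z)
  w <- alignf(list(KY = KY, Kz = Kz), y)
  expect_equal(w$mu, c(1, 0), tolerance = 1e-6)
  expect_equal(sqrt(sum(w$mu^2)), 1, tolerance = 1e-8)
  # single kernel: trivially mu = 1
  expect_equal(alignf(list(K = KY), y)$mu, 1)
  # objective at least the best single-kernel alignment
  for (i in 1:10) {
    ks <- lapply(1:3, function(.) rand_psd(n))
    wf <- alignf(ks, y)
    singles <- vapply(ks, function(K) centered_alignment(K, KY), numeric(1))
    expect_gte(wf$diagnostics$objective, max(singles) - 1e-8)
  }
})

test_that("Hadamard expansion has q(q+1)/2 PSD members with squared entries", {
  set.seed(5)
  ks <- lapply(1:4, function(i) rand_psd(7))
  ex <- qcmkl_expand(ks)
  expect_length(ex, 10)
  expect_length(qcmkl_expand(ks[1:2]), 3)
  K <- ks[[2]]
  expect_equal(ex[["K2"]], K)
  idx <- which(names(ex) == "K2*K2")
  expect_length(idx, 0)  # self-products are the originals
  # entrywise product with itself appears as K_i * K_j for i != j
  expect_equal(ex[["K1*K2"]], ks[[1]] * ks[[2]])
  for (E in ex) {
    ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("lp-MKL: uniform on identical kernels, unit p-norm, monotone trace", {
  set.seed(6)
  n <- 24
  y <- sample(c(-1, 1), n, replace = TRUE)
  K <- rand_psd(n)
  for (p in c(1.5, 2, 4)) {
    w <- lp_mkl(list(K, K, K), y, p = p, svm_C = 1)
    expect_equal(w$mu, rep(3^(-1 / p), 3), tolerance = 1e-6)
    expect_equal(sum(w$mu^p)^(1 / p), 1, tolerance = 1e-6)
  }
  for (s in 1:5) {
    set.seed(s)
    ks <- lapply(1:4, function(.) rand_psd(n))
    w <- lp_mkl(ks, y, p = 2, svm_C = 1)
    tr <- w$diagnostics$objective_trace
    expect_true(all(diff(tr) <= 1e-10))
    expect_equal(sum(w$mu^2)^0.5, 1, tolerance = 1e-6)
  }
})

test_that("small p concentrates weight on the informative kernel", {
  set.seed(7)
  n <- 30
  y <- sample(c(-1, 1), n, replace = TRUE)
  ks <- list(info = tcrossprod(y) + 0.01 * rand_psd(n),
             noise1 = rand_psd(n), noise2 = rand_psd(n))
  ks <- lapply(ks, fragkernel:::.safe_cosine)
  w_sparse <- lp_mkl(ks, y, p = 1.01, svm_C = 1)
  w_dense <- lp_mkl(ks, y, p = 5, svm_C = 1)
  expect_gt(max(w_sparse$mu / sum(w_sparse$mu)),
            max(w_dense$mu / sum(w_dense$mu)))
  expect_equal(which.max(w_sparse$mu), 1L)
})

test_that("QCMKL returns simplex weights, flips-invariant, informative kernel wins", {
  set.seed(8)
  n <- 20
  y <- sample(c(-1, 1), n, replace = TRUE)
  ks <- list(info = tcrossprod(y) + 0.05 * rand_psd(n), noise = rand_psd(n))
  ks <- lapply(ks, fragkernel:::.safe_cosine)
  w <- qcmkl(ks, y, svm_C = 1)
  expect_length(w$mu, 3)
  expect_equal(sum(w$mu), 1, tolerance = 1e-8)
  expect_true(all(w$mu >= -1e-12))
  # the label-aligned kernel family (info or its self-product) dominates
  expect_true(which.max(w$mu) %in% which(grepl("info", w$kernel_ids)))
  # flipping all labels leaves the weights unchanged (target yy' symmetric)
  w2 <- qcmkl(ks, -y, svm_C = 1)
  expect_equal(w2$mu, w$mu, tolerance = 1e-6)
})

test_that("combined kernels stay PSD for every method", {
  set.seed(9)
  n <- 15
  y <- sample(c(-1, 1), n, replace = TRUE)
  ks <- lapply(1:3, function(.) rand_psd(n))
  for (w in list(unimkl(ks), align_weights(ks, y), alignf(ks, y),
                 lp_mkl(ks, y, p = 2))) {
    Kmu <- combine_kernels(ks, w)
    ev <- eigen(Kmu, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})
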