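# Kernels on MS/MS spectra and fragmentation trees: the probability product
# kernel (PPK) on peaks/losses, loss- and node-statistics kernels, and the
# path/subtree kernels computed by dynamic programming.

.KERNEL_VARIANTS <- c("PPK_PEAKS", "PPK_LOSS", "PPK", "LB", "LC", "LI",
                      "RLB", "RLI", "NB", "NI", "CPC", "CP2", "CPK", "CSC")

#' Kernel configuration
#'
#' @param variant One of `r paste0('\x60', paste(.KERNEL_VARIANTS, collapse = '\x60, \x60'), '\x60')`.
#'   `PPK` is the pre-summed convenience `PPK_PEAKS + PPK_LOSS`.
#' @param sigma_mass Gaussian sd of the peak-mass dimension (Da).
#' @param sigma_intensity Gaussian sd of the intensity dimension (percent).
#' @param path_mode `"all_pairs"` (paths may start anywhere) or
#'   `"root_anchored"` (paths/subtrees anchored at the two roots). Default
#'   `all_pairs` for CPC/CP2/CPK and `root_anchored` for CSC (common subtrees
#'   share the intact molecular ion).
#' @param normalize Cosine-normalize the Gram matrix.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(variant = "NB", sigma_mass = 0.01,
                          sigma_intensity = 1, path_mode = NULL,
                          normalize = FALSE) {
  variant <- match.arg(variant, .KERNEL_VARIANTS)
  stopifnot(sigma_mass > 0, sigma_intensity > 0)
  if (is.null(path_mode))
    path_mode <- if (variant == "CSC") "root_anchored" else "all_pairs"
  path_mode <- match.arg(path_mode, c("all_pairs", "root_anchored"))
  structure(list(variant = variant, sigma_mass = sigma_mass,
                 sigma_intensity = sigma_intensity, path_mode = path_mode,
                 normalize = isTRUE(normalize)),
            class = "kernel_config")
}

#' The default 12-kernel bundle
#'
#' Eleven fragmentation-tree kernels plus the combined spectral PPK.
#'
#' @return Character vector of variant names.
#' @export
kernel_variants <- function() {
  c("LB", "LC", "LI", "RLB", "RLI", "NB", "NI", "CPC", "CP2", "CPK", "CSC",
    "PPK")
}

# closed-form integral of the product of two 2D Gaussians with shared
# diagonal covariance diag(sm^2, si^2)
.ppk_g <- function(dmz, dint, sm, si) {
  1 / (4 * pi * sm * si) * exp(-dmz^2 / (4 * sm^2) - dint^2 / (4 * si^2))
}

#' Probability product kernel between two spectra
#'
#' Each peak is modeled as a 2D Gaussian over (m/z, intensity) with shared
#' diagonal covariance; a spectrum is the uniform mixture of its peak
#' Gaussians and the kernel is the integral of the product of the two
#' mixtures:
#' \deqn{K = \frac{1}{\ell_a \ell_b} \sum_{k,l}
#'   \frac{1}{4\pi\sigma_\mu\sigma_\iota}
#'   \exp\!\Big(-\frac{\Delta mz^2}{4\sigma_\mu^2}
#'             -\frac{\Delta\iota^2}{4\sigma_\iota^2}\Big).}
#' For variant `PPK_LOSS` the peak coordinates are first mapped to the
#' absolute difference from the precursor, `(|prec - mz|, intensity)`;
#' `PPK` returns the sum of the peaks and loss kernels.
#'
#' @param a,b Preprocessed [ms_spectrum()] objects.
#' @param cfg A [kernel_config()] with a PPK variant.
#' @return Kernel value (0 when either spectrum is empty).
#' @export
ppk_pairwise <- function(a, b, cfg = kernel_config("PPK_PEAKS")) {
  stopifnot(cfg$variant %in% c("PPK_PEAKS", "PPK_LOSS", "PPK"))
  if (cfg$variant == "PPK") {
    return(ppk_pairwise(a, b, utils::modifyList(cfg, list(variant = "PPK_PEAKS"))) +
           ppk_pairwise(a, b, utils::modifyList(cfg, list(variant = "PPK_LOSS"))))
  }
  la <- n_peaks(a); lb <- n_peaks(b)
  if (la == 0L || lb == 0L) return(0)
  ma <- a$peaks$mz; mb <- b$peaks$mz
  ia <- a$peaks$intensity; ib <- b$peaks$intensity
  if (cfg$variant == "PPK_LOSS") {
    ma <- abs(a$precursor_mz - ma)
    mb <- abs(b$precursor_mz - mb)
  }
  g <- .ppk_g(outer(ma, mb, "-"), outer(ia, ib, "-"),
              cfg$sigma_mass, cfg$sigma_intensity)
  sum(g) / (la * lb)
}

.root_losses <- function(t, alphabet = element_alphabet()) {
  # formula differences root - v for every non-root node; unique because
  # node formulas are unique
  root <- parse_formula(t$formulas[1], alphabet)
  vapply(seq_along(t$formulas)[-1], function(i) {
    format_formula(root - parse_formula(t$formulas[i], alphabet))
  }, character(1))
}

#' Loss-based feature vectors of a fragmentation tree
#'
#' `LB` marks the presence of each loss formula, `LC` counts its
#' multiplicity, `LI` is the mean terminal-node intensity over edges with
#' that loss. `RLB`/`RLI` use the root-loss set (formula difference between
#' the root and each node; the root's own empty loss is excluded): presence
#' indicator and terminal-node intensity respectively.
#'
#' @param t A [fragtree()].
#' @param variant One of `"LB"`, `"LC"`, `"LI"`, `"RLB"`, `"RLI"`.
#' @param alphabet [element_alphabet()].
#' @return Named numeric vector (sparse: only present losses appear).
#' @export
loss_features <- function(t, variant = c("LB", "LC", "LI", "RLB", "RLI"),
                          alphabet = element_alphabet()) {
  variant <- match.arg(variant)
  n <- length(t$formulas)
  if (n < 2) return(stats::setNames(numeric(0), character(0)))
  if (variant %in% c("RLB", "RLI")) {
    rl <- .root_losses(t, alphabet)
    val <- if (variant == "RLB") rep(1, length(rl)) else t$intensity[-1]
    return(stats::setNames(as.numeric(val), rl))
  }
  losses <- t$loss[-1]
  ints <- t$intensity[-1]
  keys <- sort(unique(losses))
  val <- switch(variant,
    LB = rep(1, length(keys)),
    LC = as.numeric(table(losses)[keys]),
    LI = vapply(keys, function(l) mean(ints[losses == l]), numeric(1)))
  stats::setNames(as.numeric(val), keys)
}

#' Node-based feature vectors of a fragmentation tree
#'
#' `NB` marks the presence of each node formula; `NI` carries the node's
#' peak intensity.
#'
#' @param t A [fragtree()].
#' @param variant `"NB"` or `"NI"`.
#' @return Named numeric vector keyed by node formulas.
#' @export
node_features <- function(t, variant = c("NB", "NI")) {
  variant <- match.arg(variant)
  val <- if (variant == "NB") rep(1, length(t$formulas)) else t$intensity
  stats::setNames(as.numeric(val), t$formulas)
}

# shared loss-id encoding of two trees for the C++ DP kernels
.tree_pair_ids <- function(t1, t2) {
  dict <- unique(c(t1$loss[-1], t2$loss[-1]))
  list(p1 = ifelse(is.na(t1$parent), -1L, t1$parent - 1L),
       l1 = c(-1L, match(t1$loss[-1], dict) - 1L),
       p2 = ifelse(is.na(t2$parent), -1L, t2$parent - 1L),
       l2 = c(-1L, match(t2$loss[-1], dict) - 1L))
}

#' Common-path counting kernel (CPC)
#'
#' The dot product of path-count feature maps: for every non-empty loss-label
#' sequence, the number of downward paths with that sequence. With
#' `mode = "all_pairs"` paths may start at any node; `"root_anchored"` counts
#' only paths starting at the two roots.
#'
#' @param t1,t2 [fragtree()] objects.
#' @param mode `"all_pairs"` (default) or `"root_anchored"`.
#' @return Non-negative count.
#' @export
cpc <- function(t1, t2, mode = c("all_pairs", "root_anchored")) {
  mode <- match.arg(mode)
  z <- .tree_pair_ids(t1, t2)
  .cpc_pair_dp(z$p1, z$l1, z$p2, z$l2, mode == "root_anchored")
}

#' Common paths of length two (CP2)
#'
#' Counts pairs of two-edge downward paths with equal ordered loss sequences:
#' the dot product of loss-bigram count vectors.
#'
#' @param t1,t2 [fragtree()] objects.
#' @return Non-negative count.
#' @export
cp2 <- function(t1, t2) {
  bigrams <- function(t) {
    idx <- which(!is.na(t$parent) & !is.na(t$parent[t$parent]))
    if (!length(idx)) return(character(0))
    paste(t$loss[t$parent[idx]], t$loss[idx], sep = "\r")
  }
  b1 <- table(bigrams(t1)); b2 <- table(bigrams(t2))
  shared <- intersect(names(b1), names(b2))
  if (!length(shared)) return(0)
  sum(as.numeric(b1[shared]) * as.numeric(b2[shared]))
}

#' Common-path kernel scored by the peak PPK (CPK)
#'
#' The CPC recursion with the unit match contribution replaced by the 2D
#' Gaussian-product score of the two terminal peaks, so each pair of common
#' paths contributes the PPK similarity of its end points.
#'
#' @param t1,t2 [fragtree()] objects.
#' @param cfg [kernel_config()] supplying `sigma_mass`, `sigma_intensity`
#'   and `path_mode`.
#' @return Non-negative kernel value.
#' @export
cpk <- function(t1, t2, cfg = kernel_config("CPK")) {
  z <- .tree_pair_ids(t1, t2)
  .cpk_pair_dp(z$p1, z$l1, t1$mz, t1$intensity,
               z$p2, z$l2, t2$mz, t2$intensity,
               cfg$sigma_mass, cfg$sigma_intensity,
               cfg$path_mode == "root_anchored")
}

#' Common-subtree counting kernel (CSC)
#'
#' Counts label-isomorphic pairs of rooted subtrees (at least one edge).
#' For each pair of children with equal loss a common subtree can continue
#' below, stop at the edge, or skip the pair; the all-skip case is subtracted.
#' Default mode anchors the subtrees at the two roots (the intact molecular
#' ion); `"all_pairs"` sums over all node pairs.
#'
#' @param t1,t2 [fragtree()] objects.
#' @param mode `"root_anchored"` (default) or `"all_pairs"`.
#' @return Non-negative count.
#' @export
csc <- function(t1, t2, mode = c("root_anchored", "all_pairs")) {
  mode <- match.arg(mode)
  z <- .tree_pair_ids(t1, t2)
  .csc_pair_dp(z$p1, z$l1, z$p2, z$l2, mode == "root_anchored")
}

.feature_gram <- function(feats) {
  keys <- unique(unlist(lapply(feats, names)))
  n <- length(feats)
  if (!length(keys)) return(matrix(0, n, n))
  Fm <- matrix(0, n, length(keys))
  for (i in seq_len(n)) {
    f <- feats[[i]]
    if (length(f)) Fm[i, match(names(f), keys)] <- unname(f)
  }
  tcrossprod(Fm)
}

#' Gram matrix of a configured kernel
#'
#' Assembles the symmetric kernel matrix of one variant over a list of items
#' (spectra for the PPK variants, fragmentation trees otherwise), optionally
#' cosine-normalized: `K'(i,j) = K(i,j) / sqrt(K(i,i) K(j,j))`.
#'
#' @param items List of [ms_spectrum()] or [fragtree()] objects.
#' @param cfg A [kernel_config()].
#' @param ids Optional example identifiers (default: item `$id`s).
#' @return Symmetric numeric matrix with `ids` as dimnames.
#' @export
gram_matrix <- function(items, cfg = kernel_config("NB"), ids = NULL) {
  n <- length(items)
  if (is.null(ids)) ids <- vapply(items, `[[`, character(1), "id")
  v <- cfg$variant
  if (v %in% c("PPK_PEAKS", "PPK_LOSS", "PPK")) {
    K <- if (v == "PPK")
      .ppk_gram(items, cfg, loss_side = FALSE) +
        .ppk_gram(items, cfg, loss_side = TRUE)
    else .ppk_gram(items, cfg, loss_side = v == "PPK_LOSS")
  } else if (v %in% c("LB", "LC", "LI", "RLB", "RLI")) {
    K <- .feature_gram(lapply(items, loss_features, variant = v))
  } else if (v %in% c("NB", "NI")) {
    K <- .feature_gram(lapply(items, node_features, variant = v))
  } else if (v == "CP2") {
    # loss-bigram count vectors, one per tree, then a plain dot product
    feats <- lapply(items, function(t) {
      idx <- which(!is.na(t$parent) & !is.na(t$parent[t$parent]))
      if (!length(idx)) return(stats::setNames(numeric(0), character(0)))
      tb <- table(paste(t$loss[t$parent[idx]], t$loss[idx], sep = "\r"))
      stats::setNames(as.numeric(tb), names(tb))
    })
    K <- .feature_gram(feats)
  } else {
    # shared integer loss encoding once for the whole bundle, then straight
    # calls into the DP kernels
    dict <- unique(unlist(lapply(items, function(t) t$loss[-1])))
    ps <- lapply(items, function(t) ifelse(is.na(t$parent), -1L, t$parent - 1L))
    ls <- lapply(items, function(t) c(-1L, match(t$loss[-1], dict) - 1L))
    anchored <- cfg$path_mode == "root_anchored"
    K <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      K[i, j] <- K[j, i] <- switch(v,
        CPC = .cpc_pair_dp(ps[[i]], ls[[i]], ps[[j]], ls[[j]], anchored),
        CPK = .cpk_pair_dp(ps[[i]], ls[[i]], items[[i]]$mz, items[[i]]$intensity,
                           ps[[j]], ls[[j]], items[[j]]$mz, items[[j]]$intensity,
                           cfg$sigma_mass, cfg$sigma_intensity, anchored),
        CSC = .csc_pair_dp(ps[[i]], ls[[i]], ps[[j]], ls[[j]], anchored))
    }
  }
  dimnames(K) <- list(ids, ids)
  if (cfg$normalize) K <- cosine_normalize(K) else K
}

# vectorized PPK Gram: one big Gaussian-product matrix over the pooled peaks
# of all spectra, aggregated per spectrum pair
.ppk_gram <- function(spectra, cfg, loss_side = FALSE) {
  n <- length(spectra)
  counts <- vapply(spectra, n_peaks, integer(1))
  K <- matrix(0, n, n)
  nz <- which(counts > 0)
  if (!length(nz)) return(K)
  mz <- unlist(lapply(spectra[nz], function(s)
    if (loss_side) abs(s$precursor_mz - s$peaks$mz) else s$peaks$mz))
  ii <- unlist(lapply(spectra[nz], function(s) s$peaks$intensity))
  grp <- rep(seq_along(nz), counts[nz])
  G <- .ppk_g(outer(mz, mz, "-"), outer(ii, ii, "-"),
              cfg$sigma_mass, cfg$sigma_intensity)
  S <- rowsum(t(rowsum(G, grp)), grp)       # peak-pair sums per spectrum pair
  K[nz, nz] <- S / outer(counts[nz], counts[nz])
  (K + t(K)) / 2   # aggregation order differs across the diagonal by one ulp
}

#' Cosine-normalize a kernel matrix
#'
#' @param K Symmetric kernel matrix.
#' @return Matrix with unit diagonal; errors when a diagonal entry is zero.
#' @export
cosine_normalize <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1]
    nm <- if (!is.null(rownames(K))) rownames(K)[bad] else as.character(bad)
    stop("cannot normalize: zero self-similarity for item '", nm, "'")
  }
  K / sqrt(outer(d, d))
}

# tolerant variant used by the modelling pipeline: items with zero
# self-similarity (zero feature vectors, e.g. a star tree under the loss
# bigram kernel) get zero similarity to everything and unit self-similarity
.safe_cosine <- function(K) {
  d <- diag(K)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  K2 <- K * outer(s, s)
  diag(K2) <- 1
  K2
}

#' Compute the full kernel bundle
#'
#' Evaluates every requested variant over matched lists of spectra and trees
#' (the i-th spectrum and i-th tree describe the same compound).
#'
#' @param spectra List of [ms_spectrum()] (used by the PPK variants).
#' @param trees List of [fragtree()] (used by the tree kernels).
#' @param variants Character vector of variants; default [kernel_variants()].
#' @param sigma_mass,sigma_intensity PPK/CPK bandwidths.
#' @param normalize Cosine-normalize each matrix.
#' @return Named list of Gram matrices.
#' @export
kernel_bundle <- function(spectra, trees, variants = kernel_variants(),
                          sigma_mass = 0.01, sigma_intensity = 1,
                          normalize = FALSE) {
  out <- lapply(variants, function(v) {
    cfg <- kernel_config(v, sigma_mass = sigma_mass,
                         sigma_intensity = sigma_intensity,
                         normalize = normalize)
    items <- if (v %in% c("PPK_PEAKS", "PPK_LOSS", "PPK")) spectra else trees
    gram_matrix(items, cfg)
  })
  names(out) <- variants
  out
}

#' Write a kernel matrix as tab-delimited text
#'
#' Header row and first column carry the example ids; values are printed with
#' 17 significant digits so the round trip through [read_kernel_tsv()] is
#' bit-exact.
#'
#' @param K Kernel matrix with dimnames.
#' @param path Output path.
#' @export
write_kernel_tsv <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  lines <- c(paste(c("id", ids), collapse = "\t"),
             vapply(seq_len(nrow(K)), function(i) {
               paste(c(ids[i], sprintf("%.17g", K[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with id dimnames.
#' @export
read_kernel_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  K <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(K) <- vapply(rows, `[[`, character(1), 1)
  colnames(K) <- header
  K
}
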