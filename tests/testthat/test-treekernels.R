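test_that("PPK closed form matches its zero-distance value and quadrature", {
  cfg <- kernel_config("PPK_PEAKS", sigma_mass = 1, sigma_intensity = 1)
  a <- ms_spectrum("a", 300, 100, 50)
  expect_equal(ppk_pairwise(a, a, cfg), 1 / (4 * pi))
  # delta mz = 2, delta intensity = 0 at unit sigmas: (1/4pi) e^{-1}
  b <- ms_spectrum("b", 300, 102, 50)
  expect_equal(ppk_pairwise(a, b, cfg), exp(-1) / (4 * pi), tolerance = 1e-12)
  expect_equal(ppk_pairwise(a, b, cfg),
               quadrature_g(100, 50, 102, 50, 1, 1), tolerance = 1e-9)
  # empty spectrum convention
  e <- ms_spectrum("e", 300)
  expect_equal(ppk_pairwise(a, e, cfg), 0)
})

test_that("PPK is symmetric and the loss variant maps to precursor differences", {
  set.seed(5)
  cfg <- kernel_config("PPK_PEAKS", sigma_mass = 0.01, sigma_intensity = 1)
  for (i in 1:25) {
    a <- ms_spectrum("a", 400, sort(runif(6, 50, 400)), runif(6, 1, 60))
    b <- ms_spectrum("b", 420, sort(runif(5, 50, 420)), runif(5, 1, 60))
    expect_equal(ppk_pairwise(a, b, cfg), ppk_pairwise(b, a, cfg))
  }
  # loss variant: spectra with equal losses but shifted peaks match exactly
  lcfg <- kernel_config("PPK_LOSS", sigma_mass = 0.01, sigma_intensity = 1)
  a <- ms_spectrum("a", 400, c(300, 350), c(40, 60))
  b <- ms_spectrum("b", 500, c(400, 450), c(40, 60))  # same losses 100, 50
  expect_equal(ppk_pairwise(a, b, lcfg), ppk_pairwise(a, a, lcfg))
  # combined variant is the sum
  pcfg <- kernel_config("PPK", sigma_mass = 0.01, sigma_intensity = 1)
  expect_equal(ppk_pairwise(a, b, pcfg),
               ppk_pairwise(a, b, kernel_config("PPK_PEAKS", 0.01, 1)) +
                 ppk_pairwise(a, b, lcfg))
})

test_that("loss and node feature vectors evaluate their definitions", {
  # two H2O losses (child intensities 10 and 30) and one CO loss (5)
  root <- "C20H30N4O10S2"
  f1 <- format_formula(subtract_formula(root, "H2O"))
  f2 <- format_formula(subtract_formula(f1, "H2O"))
  f3 <- format_formula(subtract_formula(f1, "CO"))
  t <- fragtree(c(root, f1, f2, f3), c(NA, 1, 2, 2), c(50, 10, 30, 5))
  expect_equal(loss_features(t, "LB"), c(CO = 1, H2O = 1))
  expect_equal(loss_features(t, "LC"), c(CO = 1, H2O = 2))
  expect_equal(loss_features(t, "LI"), c(CO = 5, H2O = 20))
  nb <- node_features(t, "NB")
  expect_equal(unname(nb), rep(1, 4))
  ni <- node_features(t, "NI")
  expect_equal(unname(ni[t$formulas]), t$intensity)
  # single-node tree: empty loss features
  t1 <- fragtree(root, NA_integer_, 100)
  expect_length(loss_features(t1, "LB"), 0)
})

test_that("root-loss features use the root-minus-node set", {
  t <- chain_tree(c("H2O", "CO"))  # root losses: H2O and H2O+CO = CH2O2
  rlb <- loss_features(t, "RLB")
  expect_setequal(names(rlb), c("H2O", "CH2O2"))
  expect_equal(unname(rlb), c(1, 1))
  rli <- loss_features(t, "RLI")
  expect_equal(rli[["H2O"]], t$intensity[2])
  expect_equal(rli[["CH2O2"]], t$intensity[3])
})

test_that("path and subtree kernels agree with hand examples", {
  ab <- chain_tree(c("H2O", "CO"))
  ac <- chain_tree(c("H2O", "CO2"))
  expect_equal(cpc(ab, ab), 3)        # "a", "b", "ab"
  expect_equal(cpc(ab, ac), 1)        # only "a"
  single <- fragtree("C20H30N4O10S2", NA_integer_, 100)
  expect_equal(cpc(ab, single), 0)
  expect_equal(cp2(ab, ab), 1)
  expect_equal(cp2(ab, ac), 0)
  star <- star_tree(c("H2O", "CO"))
  expect_equal(cp2(star, ab), 0)
  expect_equal(csc(star, star), 3)    # (0+2)(0+2) - 1
  expect_equal(csc(ab, ac, "root_anchored"), 1)  # shared edge H2O
  chain_a <- chain_tree("H2O")
  expect_equal(csc(chain_a, chain_a), 1)
})

test_that("DP kernels equal brute-force enumeration on random tree pairs", {
  cfg <- small_tree_cfg()
  set.seed(13)
  for (i in 1:60) {
    t1 <- gen_tree(cfg, id = "t1")
    t2 <- gen_tree(cfg, id = "t2")
    expect_identical(cpc(t1, t2), oracle_cpc(t1, t2))
    expect_identical(cpc(t1, t2, "root_anchored"), oracle_cpc(t1, t2, TRUE))
    expect_identical(cp2(t1, t2), oracle_cp2(t1, t2))
    expect_identical(csc(t1, t2), oracle_csc(t1, t2, TRUE))
    expect_identical(csc(t1, t2, "all_pairs"), oracle_csc(t1, t2, FALSE))
    kc <- kernel_config("CPK", sigma_mass = 0.01, sigma_intensity = 1)
    expect_equal(cpk(t1, t2, kc), oracle_cpk(t1, t2, 0.01, 1),
                 tolerance = 1e-9)
  }
})

test_that("tree kernels are invariant under sibling permutation", {
  cfg <- small_tree_cfg()
  set.seed(17)
  for (i in 1:10) {
    t1 <- gen_tree(cfg, id = "t1")
    t2 <- gen_tree(cfg, id = "t2")
    # reverse the order of root children by rebuilding with permuted rows
    n <- length(t1$formulas)
    perm <- c(1, rev(seq_len(n)[-1]))
    inv <- match(seq_len(n), perm)
    t1p <- fragtree(t1$formulas[perm], inv[t1$parent][perm],
                    t1$intensity[perm], mz = t1$mz[perm], id = "t1p")
    expect_equal(cpc(t1p, t2), cpc(t1, t2))
    expect_equal(cp2(t1p, t2), cp2(t1, t2))
    expect_equal(csc(t1p, t2), csc(t1, t2))
  }
})

test_that("gram matrices are symmetric, PSD and normalize to unit diagonal", {
  cfg <- synthetic_config(seed = 23, n_compounds = 12, max_nodes = 8)
  set.seed(23)
  trees <- lapply(1:12, function(i) gen_tree(cfg, id = sprintf("g%02d", i)))
  spectra <- lapply(trees, gen_spectrum, noise_ppm = 5)
  for (v in c("LB", "NI", "CPC", "CSC", "PPK")) {
    kc <- kernel_config(v, sigma_mass = 0.01, sigma_intensity = 1)
    items <- if (v == "PPK") spectra else trees
    K <- gram_matrix(items, kc)
    expect_identical(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    if (all(diag(K) > 0)) {
      Kn <- cosine_normalize(K)
      expect_equal(unname(diag(Kn)), rep(1, nrow(K)))
      # Cauchy-Schwarz: normalized self-similarity dominates
      expect_true(all(Kn <= 1 + 1e-9))
    }
  }
})

test_that("normalization errors name the offending item", {
  K <- matrix(c(0, 0, 0, 2), 2, dimnames = list(c("bad", "ok"), c("bad", "ok")))
  expect_error(cosine_normalize(K), "bad")
})

test_that("kernel matrices round-trip through TSV bit-exactly", {
  set.seed(3)
  X <- matrix(rnorm(25), 5)
  K <- tcrossprod(X)
  dimnames(K) <- list(letters[1:5], letters[1:5])
  path <- tempfile(fileext = ".tsv")
  write_kernel_tsv(K, path)
  K2 <- read_kernel_tsv(path)
  expect_identical(K2, K)
})
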