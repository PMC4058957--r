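test_that("generated trees are valid and deterministic under a seed", {
  cfg <- synthetic_config(seed = 2, max_nodes = 10)
  t1 <- gen_tree(cfg, seed = 99, id = "s")
  t2 <- gen_tree(cfg, seed = 99, id = "s")
  expect_identical(t1, t2)
  set.seed(5)
  for (i in 1:50) expect_true(validate_fragtree(gen_tree(cfg, id = "v")))
  # all losses come from the vocabulary
  set.seed(6)
  t <- gen_tree(cfg, id = "voc")
  expect_true(all(t$loss[-1] %in% cfg$loss_vocabulary))
})

test_that("degenerate depth-1 trees are stars", {
  cfg <- synthetic_config(seed = 2, max_depth = 1)
  set.seed(8)
  for (i in 1:10) {
    t <- gen_tree(cfg, id = "star")
    expect_true(all(t$parent[-1] == 1))
  }
})

test_that("spectra mirror the tree nodes with controlled mass noise", {
  cfg <- synthetic_config(seed = 3)
  t <- gen_tree(cfg, seed = 42, id = "sp")
  s0 <- gen_spectrum(t, noise_ppm = 0)
  expect_equal(nrow(s0$peaks), length(t$formulas))
  expect_equal(sort(s0$peaks$mz), sort(t$mass))
  expect_equal(s0$precursor_mz, t$mass[1])
  s5 <- gen_spectrum(t, noise_ppm = 5, seed = 1)
  dev <- abs(sort(s5$peaks$mz) - sort(t$mass)) / sort(t$mass) * 1e6
  expect_true(all(dev < 30))  # well within 6 sigma
  expect_gt(max(dev), 0)
})

test_that("tree construction on noiseless spectra recovers the true nodes", {
  cfg <- synthetic_config(seed = 4, max_nodes = 9)
  al <- element_alphabet(c("C", "H", "N", "O", "S"), bounds = 40L)
  set.seed(14)
  rates <- vapply(1:15, function(i) {
    t <- gen_tree(cfg, id = "rec", alphabet = al)
    s <- gen_spectrum(t, noise_ppm = 0)
    g <- weight_edges(build_fraggraph(s, list(t$formulas[1]), 5, al),
                      edge_weight_config(), al)
    tt <- max_colorful_subtree_exact(g, t$formulas[1])
    mean(t$formulas %in% tt$formulas)
  }, numeric(1))
  expect_gte(mean(rates), 0.9)
})

test_that("fingerprint coupling behaves at both ends of beta", {
  cfg0 <- synthetic_config(seed = 5, n_compounds = 400, coupling_beta = 0,
                           label_noise = 0)
  set.seed(20)
  trees <- lapply(seq_len(cfg0$n_compounds), function(i)
    gen_tree(cfg0, id = sprintf("b%03d", i)))
  Y0 <- gen_fingerprints(trees, cfg0, seed = 21)
  balance <- colMeans(Y0 == 1)
  # beta = 0: fair coins, 3-sigma binomial band around 0.5
  expect_true(all(abs(balance - 0.5) < 3 * sqrt(0.25 / cfg0$n_compounds) + 0.02))
  # predictability from the coupled-loss indicator rises with beta: the
  # sign predictor is far above its beta = 0 control
  sign_acc <- function(Y) {
    coup <- attr(Y, "coupling")
    vapply(seq_len(ncol(Y)), function(j) {
      s <- vapply(trees, function(t) sum(coup[[j]] %in% t$loss[-1]), numeric(1))
      s <- s - mean(s)
      keep <- s != 0
      if (!any(keep)) return(NA_real_)
      mean(ifelse(s > 0, 1, -1)[keep] == Y[keep, j])
    }, numeric(1))
  }
  cfg8 <- synthetic_config(seed = 5, coupling_beta = 8, label_noise = 0)
  Y8 <- gen_fingerprints(trees, cfg8, seed = 22)
  acc8 <- mean(sign_acc(Y8), na.rm = TRUE)
  acc0 <- mean(sign_acc(Y0), na.rm = TRUE)
  expect_lt(abs(acc0 - 0.5), 0.06)   # uncoupled control sits at chance
  expect_gt(acc8, acc0 + 0.2)        # strong coupling is far from chance
})

test_that("benchmarks are self-consistent and bit-reproducible", {
  cfg <- synthetic_config(seed = 6, n_compounds = 10, m_properties = 8,
                          n_decoys = 5)
  b1 <- gen_benchmark(cfg)
  b2 <- gen_benchmark(cfg)
  expect_identical(b1, b2)
  expect_length(b1$trees, 10)
  expect_equal(nrow(b1$fingerprints), 10)
  # each true candidate sits inside its own mass window with its decoys
  for (i in 1:10) {
    win <- mass_window_filter(b1$db, b1$trees[[i]]$mass[1],
                              cfg$decoy_window_ppm)
    expect_true(b1$truth[i] %in% win$id)
    expect_equal(sum(startsWith(win$id, b1$trees[[i]]$id)), 1 + cfg$n_decoys)
  }
  # decoys always differ from the truth
  for (i in 1:10) {
    true_fp <- b1$db$fingerprints[b1$truth[i], ]
    dec <- b1$db$fingerprints[startsWith(b1$db$id, b1$trees[[i]]$id) &
                                b1$db$id != b1$truth[i], , drop = FALSE]
    expect_true(all(rowSums(dec != matrix(true_fp, nrow(dec), ncol(dec),
                                          byrow = TRUE)) >= 1))
  }
})
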