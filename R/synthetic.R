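# Seeded synthetic benchmark: random fragmentation trees over a loss
# vocabulary, spectra derived from trees with Gaussian ppm mass noise,
# fingerprints statistically coupled to tree content, and candidate
# databases with known ground truth.

#' Synthetic benchmark configuration
#'
#' Defaults are the package's reference study conditions: 150 compounds,
#' 40 fingerprint properties coupled with strength 5 to the loss content of
#' the trees, 5 ppm mass noise, and 19 decoys per compound inside a 300 ppm
#' window.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_compounds Number of compounds.
#' @param loss_vocabulary Character vector of loss formulas (default 12:
#'   the standard common-loss table plus HCN, C2H2 and C3H6).
#' @param max_depth Maximum tree depth (root = depth 0); `1` yields stars.
#' @param max_children Maximum children per node; each slot is filled with
#'   probability `p_branch`.
#' @param p_branch Branching probability per child slot.
#' @param max_nodes Cap on tree size.
#' @param noise_ppm Gaussian sd of the relative peak-mass noise (ppm).
#' @param m_properties Number of fingerprint properties.
#' @param coupling_beta Logistic coupling strength between properties and
#'   tree losses; 0 gives independent coin flips.
#' @param losses_per_property Number of vocabulary losses coupled to each
#'   property.
#' @param label_noise Probability of flipping each generated label.
#' @param n_decoys Decoys per compound in the candidate database.
#' @param decoy_window_ppm Mass window the decoys are sampled in.
#' @param decoy_flip_rate Per-bit flip probability of decoy fingerprints
#'   relative to the truth (decoys are guaranteed to differ in at least one
#'   bit).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_compounds = 150,
                             loss_vocabulary = NULL,
                             max_depth = 3, max_children = 3, p_branch = 0.6,
                             max_nodes = 12, noise_ppm = 5,
                             m_properties = 40, coupling_beta = 5,
                             losses_per_property = 2, label_noise = 0.02,
                             n_decoys = 19, decoy_window_ppm = 300,
                             decoy_flip_rate = 0.3) {
  if (is.null(loss_vocabulary))
    loss_vocabulary <- c(common_losses(), "CHN", "C2H2", "C3H6")
  loss_vocabulary <- vapply(loss_vocabulary,
                            function(s) format_formula(parse_formula(s)),
                            character(1), USE.NAMES = FALSE)
  stopifnot(p_branch >= 0, p_branch <= 1, label_noise >= 0, label_noise <= 1,
            decoy_flip_rate > 0, decoy_flip_rate <= 1, coupling_beta >= 0)
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 loss_vocabulary = loss_vocabulary, max_depth = max_depth,
                 max_children = max_children, p_branch = p_branch,
                 max_nodes = max_nodes, noise_ppm = noise_ppm,
                 m_properties = as.integer(m_properties),
                 coupling_beta = coupling_beta,
                 losses_per_property = as.integer(losses_per_property),
                 label_noise = label_noise, n_decoys = as.integer(n_decoys),
                 decoy_window_ppm = decoy_window_ppm,
                 decoy_flip_rate = decoy_flip_rate),
            class = "synthetic_config")
}

.sample_root_formula <- function(alphabet) {
  repeat {
    f <- stats::setNames(integer(length(alphabet$symbols)), alphabet$symbols)
    f["C"] <- sample(8:20, 1)
    f["H"] <- sample(seq(f["C"], 2 * f["C"] + 2), 1)
    f["N"] <- sample(0:3, 1)
    f["O"] <- sample(2:8, 1)
    if ("S" %in% names(f)) f["S"] <- sample(0:1, 1)
    if (rdbe(f, alphabet) >= 0) return(f)
  }
}

#' Generate a random fragmentation tree
#'
#' Grows a tree from a random CHNOS-like root formula by breadth-first
#' expansion: each node opens up to `max_children` child slots, each filled
#' with probability `p_branch` by subtracting a vocabulary loss that keeps
#' the child formula valid and unique within the tree. Node intensities are
#' exponential draws normalized to sum 100. Uses the current RNG state
#' unless `seed` is given.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Optional seed for a self-contained draw.
#' @param id Tree identifier.
#' @param alphabet [element_alphabet()].
#' @return A valid [fragtree()].
#' @export
gen_tree <- function(cfg = synthetic_config(), seed = NULL, id = "synthetic",
                     alphabet = element_alphabet()) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- lapply(cfg$loss_vocabulary, parse_formula, alphabet = alphabet)
  names(vocab) <- vapply(vocab, format_formula, character(1))
  for (attempt in 1:50) {
    root <- .sample_root_formula(alphabet)
    formulas <- format_formula(root)
    counts <- list(root)
    parent <- NA_integer_
    depth <- 0L
    frontier <- 1L
    while (length(frontier) && length(formulas) < cfg$max_nodes) {
      v <- frontier[1]; frontier <- frontier[-1]
      if (depth[v] >= cfg$max_depth) next
      slots <- which(stats::runif(cfg$max_children) < cfg$p_branch)
      for (s in slots) {
        if (length(formulas) >= cfg$max_nodes) break
        for (l in sample(seq_along(vocab))) {
          child <- counts[[v]] - vocab[[l]]
          if (any(child < 0) || !any(child > 0)) next
          fs <- format_formula(child)
          if (fs %in% formulas) next
          formulas <- c(formulas, fs)
          counts <- c(counts, list(child))
          parent <- c(parent, v)
          depth <- c(depth, depth[v] + 1L)
          frontier <- c(frontier, length(formulas))
          break
        }
      }
    }
    if (length(formulas) >= 2) {
      raw <- stats::rexp(length(formulas)) + 0.05
      return(fragtree(formulas, parent, intensity = raw / sum(raw) * 100,
                      id = id, alphabet = alphabet))
    }
  }
  stop("could not grow a tree from the loss vocabulary")
}

#' Derive a spectrum from a fragmentation tree
#'
#' One peak per node at the formula mass perturbed by Gaussian relative
#' noise; peak intensity equals the node intensity; the precursor is the
#' root mass.
#'
#' @param t A [fragtree()].
#' @param noise_ppm Gaussian sd of the mass noise (ppm).
#' @param seed Optional seed.
#' @return An [ms_spectrum()] with as many peaks as tree nodes.
#' @export
gen_spectrum <- function(t, noise_ppm = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mz <- t$mass * (1 + stats::rnorm(length(t$mass), 0, noise_ppm * 1e-6))
  ms_spectrum(t$id, precursor_mz = t$mass[1], mz = mz, intensity = t$intensity)
}

#' Generate fingerprints coupled to tree content
#'
#' Each property is coupled to a random subset of vocabulary losses; a
#' compound's latent score is the (cohort-centered) count of coupled losses
#' present in its tree, and the label is `+1` with probability
#' `plogis(beta * score)`, then flipped with the label-noise rate. At
#' `beta = 0` the properties are independent fair coins.
#'
#' @param trees List of [fragtree()] objects.
#' @param cfg A [synthetic_config()].
#' @param seed Optional seed.
#' @return Matrix in \{-1, +1\} (compounds x properties) with the coupled
#'   losses stored in `attr(, "coupling")`.
#' @export
gen_fingerprints <- function(trees, cfg = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(trees)
  present <- t(vapply(trees, function(t) {
    as.numeric(cfg$loss_vocabulary %in% t$loss[-1])
  }, numeric(length(cfg$loss_vocabulary))))
  colnames(present) <- cfg$loss_vocabulary
  Y <- matrix(NA_real_, n, cfg$m_properties)
  coupling <- vector("list", cfg$m_properties)
  for (j in seq_len(cfg$m_properties)) {
    feats <- sample(seq_along(cfg$loss_vocabulary),
                    min(cfg$losses_per_property, length(cfg$loss_vocabulary)))
    coupling[[j]] <- cfg$loss_vocabulary[feats]
    s <- rowSums(present[, feats, drop = FALSE])
    s <- s - mean(s)
    pr <- stats::plogis(cfg$coupling_beta * s)
    y <- ifelse(stats::runif(n) < pr, 1, -1)
    flip <- stats::runif(n) < cfg$label_noise
    Y[, j] <- ifelse(flip, -y, y)
  }
  rownames(Y) <- vapply(trees, `[[`, character(1), "id")
  colnames(Y) <- sprintf("prop_%02d", seq_len(cfg$m_properties))
  attr(Y, "coupling") <- coupling
  Y
}

#' Generate a self-consistent synthetic benchmark
#'
#' Seeds the RNG from `cfg$seed` and draws trees, spectra, fingerprints and
#' a candidate database containing each true compound plus mass-window
#' decoys whose fingerprints are noisy copies of the truth (always differing
#' in at least one bit).
#'
#' @param cfg A [synthetic_config()].
#' @param alphabet [element_alphabet()].
#' @return List with `config`, `trees`, `spectra`, `fingerprints`, `db`
#'   (a [candidate_db()]) and `truth` (compound id to true candidate id).
#' @export
gen_benchmark <- function(cfg = synthetic_config(), alphabet = element_alphabet()) {
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  trees <- lapply(seq_len(n), function(i)
    gen_tree(cfg, id = sprintf("c%03d", i), alphabet = alphabet))
  spectra <- lapply(trees, gen_spectrum, noise_ppm = cfg$noise_ppm)
  Y <- gen_fingerprints(trees, cfg)
  ids <- character(); formulas <- character(); masses <- numeric()
  fps <- list(); truth <- character(n)
  for (i in seq_len(n)) {
    tm <- trees[[i]]$mass[1]
    tid <- sprintf("%s_true", trees[[i]]$id)
    truth[i] <- tid
    ids <- c(ids, tid)
    formulas <- c(formulas, trees[[i]]$formulas[1])
    masses <- c(masses, tm)
    fps <- c(fps, list(Y[i, ]))
    half <- cfg$decoy_window_ppm * 1e-6
    for (d in seq_len(cfg$n_decoys)) {
      repeat {
        flip <- stats::runif(ncol(Y)) < cfg$decoy_flip_rate
        if (any(flip)) break
      }
      ids <- c(ids, sprintf("%s_d%02d", trees[[i]]$id, d))
      formulas <- c(formulas, trees[[i]]$formulas[1])
      masses <- c(masses, tm * (1 + stats::runif(1, -half, half)))
      fps <- c(fps, list(ifelse(flip, -Y[i, ], Y[i, ])))
    }
  }
  db <- candidate_db(ids, formulas, masses, do.call(rbind, fps))
  list(config = cfg, trees = trees, spectra = spectra, fingerprints = Y,
       db = db, truth = stats::setNames(truth, rownames(Y)))
}
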