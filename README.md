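# fragkernel

Metabolite identification from tandem mass spectra (MS/MS) by combining
**fragmentation trees**, a family of **tree and spectrum kernels**, and
**multiple kernel learning (MKL)** to predict molecular fingerprints and
rank candidate structures.

## Who this is for

Computational mass spectrometrists and method developers who want a
self-contained, testable R implementation of the fragmentation-tree /
kernel-learning identification pipeline: from an MGF peak list to a ranked
candidate list, with every stage exposed as an ordinary R function and the
core predictor as a classed model object.

## The method in brief

1. **Fragmentation trees.** Peaks of an amalgamated, filtered spectrum are
   decomposed into molecular formulas within a ppm window. A fragmentation
   graph connects explanations `u → v` whenever `u − v` is a valid non-empty
   formula (a fragment never gains atoms), nodes are colored by the peak
   they explain, and the tree is the **maximum-weight colorful subtree**
   (each peak used once) — solved exactly by dynamic programming over
   (node, color-subset) states, with a greedy fallback. Candidate parent
   formulas are ranked by their best tree score.
2. **Kernels.** Twelve similarity measures between compounds:
   the probability product kernel on spectra
   (`K(χ,χ′) = (1/ℓℓ′) Σ_{k,l} ∫ N(x; χ(k), Σ) N(x; χ′(l), Σ) dx`, in
   closed form), and eleven fragmentation-tree kernels — loss/node
   statistics (LB, LC, LI, RLB, RLI, NB, NI) as explicit feature-map dot
   products, and common-path / common-subtree counts (CPC, CP2, CPK, CSC)
   by dynamic programming.
3. **MKL + per-property SVMs.** Kernels are combined by UNIMKL (uniform),
   ALIGN / ALIGNF (centered kernel alignment with the target `YYᵀ`,
   independent or jointly maximized over `‖μ‖₂ = 1, μ ≥ 0`), QCMKL
   (convex weights over the Hadamard-expanded bundle) or ℓp-norm MKL
   (alternating wrapper with the closed-form update keeping `‖μ‖_p = 1`).
   One soft-margin SVM per fingerprint property is trained on the combined
   kernel; its out-of-fold cross-validation accuracy becomes the property's
   **reliability** p̂ⱼ.
4. **Retrieval.** A database candidate with fingerprint `y` scores
   `log P(y | ŷ, p̂) = Σ_{j: y_j = ŷ_j} log p̂_j + Σ_{j: y_j ≠ ŷ_j} log(1 − p̂_j)`
   (Poisson-binomial), within a ppm mass window of the query.

A seeded synthetic module (`gen_benchmark()`) generates trees over a
common-loss vocabulary, spectra with Gaussian ppm noise, logistic-coupled
fingerprints and decoy databases, so the whole pipeline is testable without
external data. See the methods vignette
(`vignettes/fragkernel-methods.Rmd`) for models, defaults and design
decisions.

## Worked example

```r
library(fragkernel)

bench <- gen_benchmark(synthetic_config(seed = 42, n_compounds = 40,
                                        m_properties = 20))
ker <- kernel_bundle(bench$spectra, bench$trees)   # the 12 Gram matrices
fit <- fingerid(ker, bench$fingerprints, method = "alignf",
                cv = cv_config(folds = 5, C_grid = 1, seed = 42))
print(fit)
#> Kernel fingerprint predictor (alignf): 12 kernels, 20 properties, 40 compounds
#> mean reliability: 0.699
summary(fit)
#> shared kernel weights:
#>     LB     LC     LI    RLB    RLI     NB     NI    CPC    CP2    CPK    CSC
#> 0.8625 0.0408 0.0516 0.0555 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000
#>    PPK
#> 0.4986
```

ALIGNF concentrates weight on the loss-presence kernel (LB) and the
spectral PPK — on this synthetic cohort the fingerprint properties are
coupled to neutral-loss content, so that is where the signal is. The
reliabilities (mean 0.70, quartiles 0.53–0.85) feed the retrieval score:

```r
pred <- predict(fit, ker, test_diag = lapply(ker, diag))
win <- mass_window_filter(bench$db, bench$trees[[1]]$mass[1], delta_ppm = 300)
win$fingerprints <- win$fingerprints[, match(fit$properties,
                                             colnames(bench$fingerprints))]
rank_candidates(win, pred$fingerprints[1, ], fit$reliabilities)[1:3, ]
#>          id log_score rank
#> 1 c001_true -7.384712    1
#> 2  c001_d06 -8.708644    2
#> 3  c001_d04 -9.381915    3
```

The true structure of compound `c001` ranks first among its 20 mass-window
candidates: the predicted fingerprint agrees with the truth at the reliable
positions, and the Poisson-binomial score rewards exactly that.

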