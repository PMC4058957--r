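---
title: "Fragmentation-tree kernels and multiple kernel learning: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentation-tree kernels and multiple kernel learning: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragkernel)
```

# The problem

Identifying a small molecule from its tandem mass spectrum (MS/MS) is a
central task in metabolomics. `fragkernel` implements a pipeline that goes
from raw peak lists to ranked candidate structures in four stages:

1. **Fragmentation trees.** Peaks are explained by molecular formulas, and a
   tree of fragmentation reactions is extracted from the graph of all
   explanations.
2. **Kernels.** Similarities between compounds are computed either directly
   on spectra (the probability product kernel) or on their fragmentation
   trees (loss, node, path and subtree kernels).
3. **Multiple kernel learning (MKL) + SVMs.** The kernels are combined into
   one and used to train one support vector machine per molecular-fingerprint
   property, giving a predicted fingerprint for an unknown compound.
4. **Retrieval.** Candidate structures from a database are ranked against the
   predicted fingerprint with a Poisson-binomial score that weighs each
   fingerprint position by how reliably it is predicted.

Every stage is usable on its own; the `fingerid()` fit object ties stages
3–4 together in the classic R modelling idiom (`print`, `summary`, `coef`,
`predict`).

# Fragmentation trees

## Preprocessing

Spectra measured at several collision energies are amalgamated: each
spectrum is normalized so its intensities sum to 100, peaks closer than the
merge window (default 0.1 Da) are merged at the m/z of the most intense
member with intensities summed, and the result is re-normalized. We then
keep the 30 most intense peaks and drop peaks below 0.5 % relative
intensity. The cap is applied before the relative-intensity cut; when both
constraints are already satisfied the order is irrelevant, and the chosen
order is deterministic. Ties among equally intense peaks are broken toward
lower m/z.

Peak merging is greedy in descending intensity (the most intense unassigned
peak absorbs everything within the window). A greedy rule is used because
any clustering with a fixed window is ambiguous on chains of nearby peaks;
greedy-by-intensity is deterministic and keeps the dominant peak's m/z,
which is the natural reference measurement.

## Graph construction and mass decomposition

Every peak is decomposed into candidate molecular formulas within a relative
mass window (default 10 ppm — a configuration value; typical QTOF accuracy
lies between 5 and 20 ppm). Decomposition is a bounded depth-first
enumeration over the element alphabet (default CHNOPS) with mass pruning;
per-element bounds are derived from the candidate parent formulas, since a
fragment can never gain atoms. This correctness-first enumeration is entirely
adequate at fragment-mass scale; residue-table optimizations are deliberately
not used.

Nodes of the fragmentation graph are formula explanations colored by the
peak they explain; when one formula explains several peaks, the peak with the
smallest mass deviation is kept so that node formulas are unique — which the
tree kernels later rely on. All edges compatible with element-wise
subtraction are inserted.

## Edge weights

Edges are scored on a log-likelihood scale as a sum of interpretable terms
(all coefficients live in `edge_weight_config()`):

* `log(1 + intensity)` of the child peak — more intense fragments are more
  trustworthy;
* a Gaussian log-likelihood *ratio* of the child's mass deviation in ppm
  (zero at zero deviation, `-0.5 (dev/sigma)^2`, default sigma 5 ppm). The
  ratio form, rather than the raw log-density, makes a perfectly matching
  explanation weight-neutral instead of uniformly negative, so that
  plausible edges keep positive weight and the empty tree is not trivially
  optimal;
* a linear penalty per Dalton of loss mass above ~4 proton masses — large
  single-step neutral losses are implausible;
* a configurable bonus (+1 by default) for nine standard small-molecule
  losses (H2O, CO, CO2, NH3, CH2O, C2H4, HCOOH, CH3OH, H2S);
* a penalty for radical losses, detected as half-integer RDBE (ring double
  bond equivalent), and for losses with negative RDBE;
* penalties for chemically implausible child formulas (negative RDBE, or
  hetero/carbon ratio above 6).

These defaults are design choices of this package, documented and fully
overridable; they are not fitted to any reference dataset.

## Maximum colorful subtree

The fragmentation tree is the maximum-weight subtree of the graph using each
color (peak) at most once. This problem is NP-hard; the exact solver is a
dynamic program over (node, color-subset) states, exponential in the number
of colors (C++ implementation, default limit 16 colors — 30-peak spectra
after filtering rarely exceed this once decompositions are pruned). Above the
limit a best-in greedy heuristic attaches the highest-weight feasible edge
repeatedly; its score never exceeds the exact optimum and it is deterministic.
Negative-weight edges are never forced: a bare root has score 0. Among
co-optimal trees the solver returns the first maximizer in a fixed iteration
order, so results are reproducible run to run.

Candidate parent formulas are ranked by the best tree score achievable with
that formula at the root; one shared graph is built for all candidates since
reachability from a candidate's root automatically restricts the graph to
its sub-formulas.

# Kernels

Twelve kernels are evaluated per compound pair (`kernel_variants()`):

* **PPK** — each peak is a 2D Gaussian over (m/z, intensity) with shared
  diagonal covariance `diag(sigma_mass^2, sigma_intensity^2)`; the spectrum
  is the uniform mixture of its peaks and the kernel is the closed-form
  integral of the product of two mixtures. The mass bandwidth should match
  the instrument tolerance (default 0.01 Da); the intensity bandwidth
  (default 1, percent scale) is a cross-validation candidate. A loss-side
  variant maps peaks to their precursor differences first; the shipped
  `PPK` variant is the sum of the peak and loss kernels, which is the usual
  spectral baseline. The zero-distance value is
  `1/(4 pi sigma_mass sigma_intensity)`.
* **LB, LC, LI** — presence, multiplicity, and mean terminal intensity per
  loss formula.
* **RLB, RLI** — the same ideas on the root-loss set (root formula minus
  node formula).
* **NB, NI** — presence and intensity per node formula.
* **CPC, CP2, CPK** — counts of common downward paths (identical loss
  sequences), restricted to two-edge paths for CP2, and scored by the peak
  PPK of the terminal nodes for CPK.
* **CSC** — counts of common (edge-labeled, rooted) subtrees.

All kernels are defined semantically as dot products of explicit feature
maps — path counts, subtree counts, loss statistics — which guarantees
positive semidefiniteness; the dynamic programs are an implementation detail
and the test suite checks them against brute-force enumeration of paths and
subtrees. Loss identity is exact formula equality: trees are symbolic
objects, so no mass-tolerance matching between trees is performed.

Two aggregation modes exist for the path/subtree kernels: `all_pairs`
(paths may start anywhere; the default for CPC/CP2/CPK) and `root_anchored`
(anchored at the two roots; the default for CSC, because a common subtree
shares the intact molecular ion). Both are exposed.

Intensities entering LI/RLI/NI are on the preprocessed 0–100 percent scale,
not re-normalized per tree.

# Multiple kernel learning

Given kernels `K_1..K_q` and fingerprint labels `Y` in {-1,+1}^(n x m), the
package implements:

* **UNIMKL** — equal weights; the hard-to-beat baseline.
* **ALIGN** — each kernel weighted by its centered alignment with the target
  kernel `K_Y = Y Y'`, i.e. the cosine of double-centered matrices under the
  Frobenius inner product.
* **ALIGNF** — jointly maximizes the alignment of the convex combination
  over the non-negative unit sphere. This is solved as the equivalent
  non-negative least-squares problem in the Gram matrix of centered kernels
  (eigen square root + NNLS) rather than as a cone program: with q around
  12 the QP is tiny and the NNLS route is robust. Tests verify optimality
  against dense random search over the feasible set.
* **QCMKL** — the bundle is enriched with all pairwise Hadamard products
  (q(q+1)/2 kernels, PSD by the Schur product theorem) and convex weights
  are learned on the expanded set. The semidefinite-programming formulation
  in the literature is an optimization route for the same soft-margin
  objective; here the simplex-constrained alternating wrapper is used, which
  avoids a heavyweight SDP dependency.
* **lp-norm MKL** — alternating wrapper: solve the SVM dual on the current
  combination, compute `||w_k||^2 = mu_k^2 alpha' G(K_k) alpha` with
  `G(K) = diag(y) K diag(y)`, then apply the closed-form update
  `mu_k = ||w_k||^{2/(p+1)} / (sum ||w||^{2p/(p+1)})^{1/p}`, which keeps
  `||mu||_p = 1`. The update is the standard one for the lp-norm framework;
  the objective trace is non-increasing, which the tests check to tight
  tolerance. The inner dual is solved by interior point (`kernlab::ipop`)
  followed by a KKT polish on the free set, so that the monotonicity of the
  alternating scheme is visible at near machine precision rather than
  obscured by solver noise.

ALIGN/ALIGNF learn one shared weight vector from `Y Y'` for all properties;
QCMKL and lp-MKL depend on the SVM and are fit per property.

Kernels are cosine-normalized before MKL by default — alignment scores and
weight scales are otherwise dominated by raw kernel magnitude (the intensity
kernels live on a scale of thousands, the binary ones on tens). The pipeline
uses a tolerant normalization in which an item with zero self-similarity
(for example a star tree under the loss-bigram kernel, which has no two-edge
path) is treated as the zero feature vector: zero similarity to everything,
unit self-similarity. The exported `cosine_normalize()` keeps the strict
contract and errors on zero diagonals.

# Fingerprint prediction and retrieval

One soft-margin SVM per fingerprint property is trained on the combined
kernel (`kernlab`, precomputed kernel matrices). The soft-margin parameter
is selected from a grid (default `2^-3 .. 2^7`) by training accuracy, taking
the smallest C among ties for determinism. Properties with class bias at or
above 0.9 are dropped: a majority-class predictor is already accurate there,
and such bits carry no retrieval signal.

Each property's **reliability** is its out-of-fold accuracy under 5-fold
cross-validation *within the training set*, so test compounds never leak
into reliabilities. Fold assignment is by compound, drawn once from the
configured seed and shared across all properties and kernels, so method
comparisons see identical splits.

Retrieval scores a candidate fingerprint `y` against the prediction
`y_hat` as `sum_j log p_j` over agreeing positions plus `sum_j log(1-p_j)`
over disagreeing ones — the log Poisson-binomial probability of the
candidate under independent per-bit reliabilities. Reliabilities are clamped
to `[1e-3, 1 - 1e-3]` so properties with perfect cross-validation folds
cannot produce infinite scores. Candidates come from a mass window around
the query mass, interpreted in ppm (a Dalton-absolute mode exists). Ties are
broken by lexicographic candidate id for reproducible ranks. With equal
reliabilities the ranking reduces to Hamming-distance ordering, which the
tests check.

Micro-averaged accuracy and F1 pool all compound-by-property cells. Method
comparisons use the exact one-sided sign test over per-property scores
(ties dropped, `stats::binom.test`); paired t-tests go through
`stats::t.test` rather than bespoke code.

# The synthetic benchmark

Real reference spectra with curated fingerprints are large external
resources; the package instead ships a seeded generator whose defaults are
the study conditions used for validation:

* 150 compounds; random CHNOS-like root formulas (C 8–20, H up to 2C+2,
  N 0–3, O 2–8, S 0–1, non-negative RDBE);
* trees grown breadth-first over a 12-loss vocabulary (the nine common
  losses plus HCN, C2H2, C3H6), up to depth 3, at most 12 nodes, branching
  probability 0.6 per slot, exponential intensities normalized to 100;
* spectra with one peak per node and Gaussian relative mass noise of 5 ppm;
* 40 fingerprint properties, each coupled to two vocabulary losses through
  a logistic model with strength beta = 5 on the cohort-centered presence
  count, plus 2 % label noise — at beta = 0 the properties are fair coins,
  and the logistic (rather than deterministic) coupling makes reliabilities
  take non-trivial values in (0.5, 1);
* a candidate database with 19 decoys per compound inside a 300 ppm mass
  window, decoy fingerprints being per-bit flips of the truth at rate 0.3,
  resampled so a decoy never equals the truth (an identical copy would not
  be a decoy).

What the generator does *not* emulate: real fragmentation chemistry (losses
are drawn at random, not mechanistically), instrument-specific noise and
intensity response, shared substructures between related metabolites, and
correlated fingerprint bits. Consequently the node kernels (NB/NI), which
dominate on real data where compounds share fragments, are weak here —
synthetic node formulas rarely coincide across compounds — and the
loss-based kernels carry the signal. Passing the end-to-end tests therefore
demonstrates that the machinery is correct and that information flows
through the pipeline, not that real-data accuracy figures are reproduced.

# Validation sizes and numerical choices

The test suite validates, among others: all four DP kernels against
brute-force path/subtree enumeration (200 random tree pairs of up to 8
nodes); the exact colorful-subtree solver against exhaustive subset search
(200 random graphs, up to 14 nodes / 8 colors); the PPK closed form against
numerical quadrature (50 random peak pairs, 1e-6 relative); ALIGNF against
10,000-point random search on 40 instances; and the end-to-end benchmark at
the full study conditions (20 seeds, 150 compounds, 40 properties, 12
kernels, 5-fold CV). The end-to-end benchmark fixes C = 1 instead of the
11-point grid: the comparison is between kernel combinations under identical
protocols, and grid tuning — exercised separately in the unit tests —
multiplies the cost roughly elevenfold without changing the comparison.

Other numerical conventions: ALIGNF's Gram matrix gets a 1e-10 relative
ridge before factorization; the SVM dual inside the MKL wrappers uses a
1e-10 ridge, interior-point precision `sigf = 9`, and KKT polishing; the
lp-MKL wrapper stops at relative objective change 1e-4 (maximum 100
iterations, error on non-convergence); reliabilities clamp at 1e-3;
kernel matrices serialize at 17 significant digits so text round trips are
bit-exact.

# Known limitations

* The edge-weight coefficients are sensible defaults, not maximum-likelihood
  estimates from reference data; formula ranking on real spectra would
  benefit from fitted weights.
* The exact tree solver is exponential in the number of peaks; spectra with
  more than `exact_color_limit` distinct peaks fall back to the greedy
  heuristic (an ILP plug-in would be the natural extension).
* Charge handling is out of scope: spectra are assumed singly charged
  positive mode with adduct handling upstream.
* Isotope patterns, retention times and structure-based post-processing of
  tied candidates are not integrated.
* QCMKL's expanded bundle grows quadratically in q; with many kernels the
  per-property fits become the dominant cost.
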