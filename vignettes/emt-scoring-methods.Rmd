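---
title: "Scoring multi-program EMT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-program EMT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtscape)
```

This vignette is the package's own account of its methods: what each model
assumes, which parameters matter and why their defaults are what they are,
what the synthetic generators do and do not emulate, and where the design
was genuinely open.

## 1. The scoring problem

An epithelial–mesenchymal transition (EMT) analysis starts from a genes ×
samples expression matrix and two gene sets: an epithelial (E) program
(junctions, polarity) and a mesenchymal (M) program (motility, EMT
transcription factors). A per-sample *score* summarizes each program's
activity. The difficulty is that mesenchymal activation is not unitary:
different sample groups can upregulate different subsets of M genes, and a
single M score averages those *divergent programs* away. The package's
default scorer is built to expose them.

## 2. Nonnegative PCA

### Model

On the column-centered samples × genes submatrix $X$ of one gene set, each
axis solves

$$\max_{w \ge 0,\; \|w\|_2 = 1} \operatorname{Var}(Xw).$$

The nonnegativity constraint is the substance: an unconstrained PC mixes
up- and down-regulation into one contrast, whereas a nonnegative loading
vector can only describe *coordinated upregulation* of a gene subset. Two
divergent M programs then surface as two axes with disjoint supports, and
`top_loading_genes()` reads off the genes driving each.

### Algorithm

`fit_nnpca()` uses projected power iteration: $w \leftarrow
\Pi_+(X^\top X\, w)$, where $\Pi_+$ clips negatives and renormalizes (with
an argmax-indicator fallback when everything is nonpositive, lowest index
on ties, so the projection is total). Convergence is declared when the
Euclidean change in $w$ falls below `tol` ($10^{-8}$); `max_iter` (500)
caps the solve, and non-convergence is recorded per axis and warned, never
fatal — on structureless data the iteration can wander between
near-equivalent axes long after the score variance has stabilized.

The constrained problem is non-convex, so the starting point matters. The
solver uses a deterministic start portfolio: the projected classical
leading singular vector of the current residual (sign chosen so the
larger-absolute-mass half is positive), its projected negation, and the
single-gene axes of the highest-variance genes (up to 50); the start with
the best final objective wins. The portfolio was adopted after observing
that the singular-vector start alone can land in a local optimum on
unstructured matrices — the suite verifies the fitted axis matches or
beats a $10^5$-direction random search over the nonnegative sphere.
Seeded random restarts (`restarts`) are available on top but are not
needed for the default to pass that check.

### Deflation and ranking

After each axis, the data are deflated, $X \leftarrow X - t w^\top$ with
$t = Xw$, and the next axis is fit on the residual. Variance explained is
always reported against the total centered variance of the *original*
matrix, so fractions are comparable across axes and sum to at most 1.
Because deflation acts on the data rather than the covariance, scores of
successive axes are approximately — not exactly — uncorrelated.

Axes are reported sorted by variance explained. Extraction order and
variance order almost always coincide, but the non-convex solve can
(rarely, on unstructured data) leave a later residual axis with slightly
more variance than an earlier suboptimal one; since the ranked-variance
ordering is the product contract (M1 is *the* leading M program), the
report order follows varexp.

Genes are centered but not variance-scaled before the fit: scaling
reweights which M genes dominate M1 and makes loadings harder to compare
with expression effect sizes. An opt-in scale flag was considered and
rejected as a default for that reason.

## 3. The per-sample backends

Four single-axis scorers complement nnPCA, all invariant to the order
genes appear in the matrix:

* **ssGSEA** — genes ranked by expression descending (ties broken by gene
  name, so the statistic is deterministic); the score is the sum over rank
  positions of the difference between the weighted in-set ECDF (weights
  $|x|^\alpha$, $\alpha = 0.25$) and the unweighted out-of-set ECDF. Raw
  scores are returned by default; cohort-wide min–max rescaling is an
  explicit flag because it makes scores dataset-dependent.
* **AUCell** — area under the set's recovery curve within the top
  `top_fraction` (5%) of the ranking, normalized by the perfect-recovery
  area, so the score lies in $[0,1]$. Ties are broken by a seeded
  permutation keyed on gene names (recorded in metadata), keeping scores
  row-order invariant.
* **SCSE** — $100 \times$ the set's share of the sample's total
  expression; scale-free by construction.
* **JASMINE** — mean ascending rank of the expressed set genes among all
  expressed genes, divided by the number of expressed genes; or the
  enrichment odds ratio of expressed/unexpressed × set/non-set with a
  Haldane 0.5 correction on zero cells. Each variant is min–max scaled
  across samples; `combined` averages the two scaled variants.

`em_scores()` fits the E set and the M set separately (two independent
axes, not a forced trade-off); with nnPCA the M fit returns `K_m` ranked
axes (default 2, exposing M1 vs M2). nnPCA and SCSE require normalized
input (`normalize_matrix()`, counts-per-10,000 then `log1p` — the
single-cell convention; the 10,000 scale factor is configurable); the
rank-based backends accept raw counts too. Scores from nnPCA are centered
at the data mean, so negative values simply mean "below average for this
dataset".

## 4. EMT states

`fit_gmm_states()` clusters samples in (E, M1) space with Gaussian
mixtures with full per-component covariances — E–M clouds are elongated
and tilted, and spherical components would shred them. K runs over 2–6
and is selected by BIC (fit via *mclust*, whose model-based hierarchical
initialization is deterministic; the `n_init` argument is retained for
interface stability but inert). Components are labeled on z-scored
coordinates by their mean $\tilde M - \tilde E$: minimum = Epithelial,
maximum = Mesenchymal, intermediates = Hybrid-$i$ ascending. Z-scoring
makes "extreme relative to the dataset" operational and the labels
invariant to any affine rescaling of the score axes. Hybrids exist only
for $K \ge 3$; a forced $K = 2$ yields E and M only. Hard assignments take
the maximum responsibility; the full posterior is retained.

`map_labels()` cross-tabulates any annotation column against the states,
ordered Epithelial → Hybrids → Mesenchymal, emitting link records ready
for a Sankey renderer. `score_trend()` sorts by pseudotime (or any
ordering), reports a centered rolling mean (window
$\max(5, \lceil 0.05\,n\rceil)$ samples) and the Spearman rank correlation
— Spearman because pseudotime is ordinal, not metric.

## 5. Screening

`screen_collection()` scores every set of a GMT collection (nnPCA PC1 by
default) and ranks by Pearson correlation with the supplied EMT score
(the M1 column by default, matching the package's default pipeline). Sets
whose overlap with the reference M set exceeds 30% are filtered first:
their correlation is guaranteed by shared genes, not biology. The overlap
denominator is the *candidate* set's size — a small candidate dominated by
EMT genes is caught even against a large reference — with `reference` and
`jaccard` denominators available. Because nnPCA loadings are nonnegative,
each screened set's score direction is "coordinated upregulation of the
set", so the sign of the correlation is directly interpretable. Sets that
cannot be scored (too few matched genes, degenerate score) are recorded
with a skip status and a reason, never dropped; Benjamini–Hochberg
q-values are reported for the scored correlations but play no part in the
ranking, which follows r alone, as ranked correlations are the product.

## 6. Synthetic data: what it does and does not show

The generators produce the structures the analyses are built to detect,
with all randomness under a single seed.

* `generate_timecourse()` plants a latent progression $p \in [0,1]$ per
  cell, Beta-distributed with mean rising from 0.1 to 0.9 across time
  points (concentration 12). Within-time-point spread is the point: hybrid
  cells concentrate at transition times instead of mapping hard onto time
  labels. E genes fall log-linearly in $p$, M genes rise
  (`effect` = 2 natural-log-fold), background stays flat; Gaussian
  log-noise (sd 0.4) is added and counts are Poisson-sampled from the
  log-normal means. Defaults (2000 cells × 1000 genes, 50 + 50 E/M genes,
  time points 0/1/2/4/7) are sized like a small induction experiment. Two
  extra 40-gene "bystander" blocks track $p$ and $1-p$ while staying
  disjoint from the E/M sets — they are what a screen should find.
* `generate_divergent_programs()` builds a 120-sample cohort in three
  groups: program 1 up in group Y, program 2 up in group AN (at 0.8× the
  effect, so the variance ranking M1 = program 1 is determined rather than
  left to a coin flip), E genes up in the E-like group.
* `generate_state_mixture()` draws (E, M1) scores directly from three
  isotropic Gaussians along the E→M diagonal (means (2,−2), (0,0), (−2,2),
  sd 0.5) for exercising state detection against a known assignment.

What passing these tests shows: the solver finds planted variance
structure, the mixture machinery recovers separated states, the screen
ranks genuinely tracking sets first. What it does not show: robustness to
scRNA-seq dropout, batch structure, library-size extremes or ambient
contamination — none of which are modeled (Poisson counts only;
negative-binomial overdispersion is deliberately out of the default).
Results on real data depend on normalization and gene-set quality in ways
no synthetic check can certify.

## 7. Numerical choices and degenerate inputs

* Gene symbols are upper-cased at parse time (mixed-case human/mouse
  collisions); duplicate matrix rows collapse by *summation* (count
  semantics), with a warning.
* Matrix orientation is never auto-detected; samples-as-rows input needs
  an explicit `transpose = TRUE` (silent auto-transpose corrupts
  square-ish matrices).
* `min_genes` defaults to 5: below that, a PCA axis on the subset is
  dominated by single-gene noise.
* All-zero samples normalize to all-zero with a warning; zero-total
  samples score 0 under SCSE; constant score vectors make a screened set
  skipped rather than crashing the screen.
* Centering is validated (`|gene mean| ≤ 10^{-6}` × data scale) before an
  nnPCA fit; non-centered input is an error, not a silent fix.
* Determinism: every stochastic step (AUCell ties, random restarts,
  generators) runs under an explicit seed and restores the caller's RNG
  state; identical inputs and seed give identical results, which the suite
  asserts down to file bytes for the CLI.

## 8. Problem sizes in the checks

The test suite and acceptance script size their simulations for a
single-CPU run: 20 random 5-gene × 60-sample matrices against a
$10^5$-direction random search; 10 divergent cohorts (120 × 500); 20
planted state mixtures (n = 300); the default 2000 × 1000 time course plus
20 effect-free null courses at n = 1000; and a 51-set screen. These sizes
were chosen so each property is tested at the scale its estimator
stabilizes, while the whole suite stays in the low minutes.

## 9. Known limitations

* No HDF5/10x-h5 reader: ingestion is delimited text and sparse triplet
  (plus sidecars). Serialized R single-cell objects are likewise out of
  scope — export to text first.
* Pseudotime is consumed, never inferred.
* Screen correlations come without permutation nulls; the optional
  q-values assume the usual Pearson sampling theory, which
  pseudo-replicated single-cell data violate.
* nnPCA axes from data deflation are only approximately uncorrelated, and
  the solver is a heuristic for a non-convex problem: the random-search
  check bounds how far from optimal it can be on small problems, not on
  arbitrarily large ones.
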