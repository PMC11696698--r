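---
title: "Cell-type deconvolution by non-negative least squares: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type deconvolution by non-negative least squares: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

## The problem and the model

A capture spot in sequencing-based spatial transcriptomics pools the mRNA
of the handful of cells sitting on it, so its measured counts are a
mixture of cell-type expression programs. With a labelled scRNA-seq
reference in hand, deconvolution asks: what fraction of each cell type
contributes to each spot?

`spotdecon` models the spot-by-gene count matrix $Y$ ($n_s \times n_g$)
as a weighted sum of *prototypes* — the individual reference cell
profiles forming the rows of $X$ ($n_c \times n_g$):

$$Y = M X + E, \qquad M \in \mathbb{R}^{n_s \times n_c},$$

with $E$ unstructured noise. Regressing on prototypes rather than on
per-type mean profiles keeps within-type heterogeneity in the design:
a type represented by 150 diverse cells contributes 150 columns of $M$,
and any non-negative combination of them can explain a spot. The
per-type proportion at spot $i$ is the share of that type's prototypes
in the spot's total weight,

$$\hat P_{ik} = \frac{\sum_{j \in \text{type } k} \hat M_{ij}}{\sum_j \hat M_{ij}},$$

which places every spot's estimate on the probability simplex. Note the
model uses no spatial smoothing: each spot is deconvolved from its own
counts, and the coordinates only matter for plotting.

## The two estimators

**NNLS.** The reference estimator solves

$$\hat M = \arg\min_{M \ge 0} \tfrac12 \lVert Y - MX \rVert_F^2 +
\tfrac{\lambda}{2} \lVert M \rVert_F^2$$

by projected gradient descent: a gradient step
$M \leftarrow M - \mathrm{lr}\,[(MX - Y)X^\top + \lambda M]$ followed by
clamping negatives to zero. The objective is convex (strongly convex for
$\lambda > 0$), so with a step size below the curvature limit
$2/\lVert XX^\top + \lambda I \rVert$ the iteration converges to the
global constrained minimum. The iterate starts at the elementwise
non-negative part of the OLS solution (`warm_start = TRUE`), which is
feasible and typically near-optimal, and runs for exactly `epochs`
iterations — there is no early stopping, so a run is a pure function of
its inputs. Convergence is *verified*, not assumed: the test suite
checks the Karush–Kuhn–Tucker conditions (non-negative gradient on zero
entries, vanishing gradient on positive entries) and agreement with an
independent active-set solver.

**SLS.** The fast variant skips the constraint during estimation:
closed-form OLS $\hat M = Y X^\top (X X^\top)^{-1}$, then per-spot
*type sums* are soft-thresholded at zero before normalization,

$$\hat P^{\mathrm{SLS}}_{ik} = \frac{\big(\sum_{j \in \text{type } k} \hat M_{ij}\big)_+}
{\sum_k \big(\sum_{j \in \text{type } k} \hat M_{ij}\big)_+}.$$

Clamping the sums, not the individual entries, lets negative and
positive weights within a type cancel first; when the OLS weights are
already non-negative the two estimators coincide (a tested identity).
SLS is tuning-free and runs in milliseconds at desk scale.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.1 | ridge penalty; a vector triggers cross-validation |
| `lr` | 0.1 | gradient step size (unitless; must be below the curvature limit) |
| `epochs` | 1000 | fixed iteration count of the projected gradient loop |
| `warm_start` | `TRUE` | start from clamped OLS instead of zero |
| `n_fold` | 5 | folds of the gene-split cross-validation |
| `cellcount_min` | 2 | minimum cells for a reference type to be kept |
| `gene_top` | 200 | genes kept per one-vs-rest comparison |

The cross-validation grid `seq(0, 0.2, by = 0.02)` is the package's
standard 11-point grid. Analyses in this vignette and the acceptance
script use `lr = 0.01` with 1000 epochs, the settings at which the
solver's convergence properties are verified by the test suite; the
larger default `lr = 0.1` is fine on preprocessed (per-cell normalized)
references, where the curvature of $XX^\top$ is small, and converges
faster.

## Selecting the penalty by gene-split cross-validation

Held-out validation for this model cannot split *spots* (each spot is
its own regression problem), so the split is over **genes**, the columns
shared by $X$ and $Y$: fit $\hat M$ on training genes, then score
$\tfrac12 \tfrac{1}{n_{g,\mathrm{test}}}\lVert Y_{\mathrm{test}} -
\hat M X_{\mathrm{test}} \rVert_F^2$ on held-out genes. Genes are
shuffled once with the run seed and cut into `n_fold` contiguous blocks;
the selected $\lambda$ minimizes the mean score, with ties broken toward
the smaller value (less bias when indifferent). After selection the
model is refitted on the full gene set. On noiseless data the zero
penalty reconstructs held-out genes exactly, so the procedure must and
does select $\lambda = 0$ — one of the acceptance checks.

## Preprocessing

Three ordered steps, applied to gene-aligned inputs:

1. **Per-cell normalization** — each reference cell is divided by its
   total counts, removing library-size differences between prototypes.
   Zero-total cells are dropped with a warning. Spatial counts are left
   raw: normalization standardizes the *reference profiles*; the spot
   library size ends up in the scale of $M$ and cancels in $\hat P$.
2. **Rare-type filtering** — types with fewer than `cellcount_min`
   cells are removed; a type represented by one cell gives an
   untestable one-vs-rest comparison and an unstable signature.
3. **Marker selection** — per type, genes are ranked by a one-vs-rest
   Wilcoxon rank-sum statistic (tie-corrected, computed on `log1p`
   expression, upregulated-in-type first); the union of each type's top
   `gene_top` genes is kept, sorted by gene identifier. The rank-sum
   statistic was chosen as the field's standard robust two-sample test
   for scRNA-seq marker detection; a Welch $t$ alternative is exposed
   via `method = "ttest"`. Ranking ties break lexicographically by gene
   identifier, making the marker set deterministic and invariant to
   cell order (both tested). The `log1p` transform does not affect the
   rank test but makes the $t$ alternative comparable.

Gene alignment itself is exact case-sensitive string matching on
identifiers, with the intersection sorted lexicographically; duplicate
identifiers are rejected rather than merged, since merging would guess
at the semantics of the duplication. Alignment happens *before* marker
selection, so markers are only chosen among genes observable in both
data sets.

## Numerical choices and degenerate inputs

* **Rank-deficient references.** $XX^\top$ is singular whenever
  prototypes are duplicated (and in the noiseless synthetic benchmark,
  where all cells of a type are identical). OLS then uses the
  Moore–Penrose pseudo-inverse — the minimum-norm solution, which
  splits a type's weight equally among its identical prototypes and is
  flagged on the result (`pseudo_inverse = TRUE`). The per-type sums,
  and hence the proportions, are unaffected by how the split is made.
* **Zero-weight spots.** If a spot ends up with no positive type
  weight (all-zero counts, or all type sums clamped away), the
  proportion row is undefined; such spots get a uniform $1/K$ row, a
  warning naming them, and an entry in the `fallback_spots` attribute,
  keeping the output on the simplex for downstream metrics and plots.
* **Divergence detection.** The projected-gradient loop checks its
  iterates and objective at trace checkpoints (every 100 epochs) and
  raises an error advising a smaller `lr` if they become non-finite.
  With clamping, a too-large step more often oscillates than
  overflows; the objective trace stored on the result makes that
  visible.
* **Ties in cross-validation** go to the smallest $\lambda$;
  column-name order of every proportions table is lexicographic in the
  type names, so outputs are stable across runs and estimators.

## What the synthetic generator emulates — and what it does not

`simulate_mixture()` draws one signature per type from a symmetric
Dirichlet over genes (concentration `signature_alpha = 0.1`, giving the
sparse, well-separated programs typical of distinct cell types), cells
as Poisson draws around `cell_depth` times their type's signature
(2000 counts per cell, a typical UMI depth), and spots as Poisson draws
around `spot_depth` times a signature mixture (10⁴ counts, Visium-like)
with mixing proportions from a flat Dirichlet on the simplex. The
default scale — 3 types, 50 cells per type, 300 genes, 100 spots — is
large enough to exercise marker selection and 5-fold gene splits while
keeping a full run in seconds. `noise = "none"` returns the exact
expectations, the regime in which recovery must be (and is) exact to
numerical precision.

The generator deliberately omits several features of real tissue:
platform artifacts (spot-size variation, segmentation error, bleed-over),
zero inflation beyond Poisson sampling, batch effects between reference
and spatial assays, spatial autocorrelation of composition, and
within-type expression gradients (cells of a type share one signature).
Passing the synthetic benchmarks therefore demonstrates correctness of
the estimators and their implementation — not robustness to
reference/tissue mismatch, which on real data should be judged with the
marker-gene correlation metric that needs no ground truth.

## Evaluation metrics

With ground truth: pooled RMSE over all spot-by-type entries, and the
mean per-spot Jensen–Shannon divergence in log base 2, so 0 means
identical compositions and 1 means disjoint point masses. Pooling RMSE
over entries (rather than averaging per-spot RMSEs) is the common
convention and coincides with it when shapes match. Without truth: per
type, the Pearson correlation across spots between the estimated
proportion and the mean library-size-normalized expression of that
type's marker genes; types with constant columns are reported `NA` and
excluded from the mean with a warning. The unweighted mean over a
type's markers is a convention, stated here because other summaries
(sum, weighted mean) would change the numbers slightly.

## Known limitations

* Estimation ignores spatial structure by design; neighboring spots are
  deconvolved independently.
* Proportions are relative mRNA contributions, not cell counts; types
  with more total mRNA per cell are over-represented relative to their
  cell numbers.
* The ridge penalty is shared across spots and types; per-type
  regularization is not supported.
* Very large references make the $n_c \times n_c$ Gram matrix the
  memory bottleneck; the implementation targets desk-scale analyses.
* File input is delimited text (CSV/TSV counts plus metadata tables);
  HDF5-based single-cell containers should be exported to text first.
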