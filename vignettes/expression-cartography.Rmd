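---
title: "Expression cartography with somatlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression cartography with somatlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatlas)
```

## The model

`somatlas` treats a genes × samples expression matrix as a cloud of N
points (gene profiles) in M-dimensional sample space and summarizes it by
a self-organizing map: K metagene profiles arranged on a planar
rectangular x × y grid. Training is the classic sequential Kohonen
algorithm — present one gene, find the codebook row of minimal Euclidean
distance (the best-matching unit), and pull the BMU and its Gaussian grid
neighborhood toward the gene — so that after convergence (i) every gene
has a nearby metagene, (ii) neighboring metagenes are similar, and (iii)
codebook density follows data density. Property (ii) is what turns a
per-sample codebook column into a smooth mosaic portrait; property (iii)
is why dense co-expression modules condense into compact, high-contrast
spots.

The input to training is differential expression
$\Delta e_{g,m} = e_{g,m} - \langle e_g \rangle_m$ with $e = \log_{10} E$:
centering removes each gene's absolute expression level, so the map
organizes by *profile shape* and portraits read directly in logged
fold-change units relative to the gene's mean state. Centering is the one
non-negotiable preprocessing step (`train_som()` refuses uncentered
input); log transform and quantile normalization are applied before it
when the input is raw.

### Assumptions

* Profiles are complete — no missing values (rows with NAs are rejected at
  load rather than imputed, because the Euclidean BMU criterion has no
  principled treatment of missingness).
* Samples are comparable after normalization; the centering step makes
  every gene's mean the reference state, so the portraits show deviation
  from the series average, not absolute abundance.
* Co-expression implies functional relatedness (guilt by association) —
  the justification for reading spot-level gene-set overrepresentation
  biologically.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid `x = y` | 60 (pipeline default 20) | tiles | Spot counts stabilize once the side length exceeds ~50 for genome-scale input; the package-level pipeline default of 20 suits the bundled 2,000-gene fixture and keeps examples fast. |
| schedule, phase 1 | radius x/2 → 3, α 0.05 → 0.02, 2 epochs | grid units / — | Ordering phase: a wide neighborhood untangles the initial map. Conventional Kohonen values; the source method cites the standard algorithm without parameters. |
| schedule, phase 2 | radius 3 → 1, α 0.02 → 0.01, 2 epochs | | Fine-tuning with a narrow neighborhood. The starting radius is floored at 3 so tiny grids keep a valid (non-increasing) schedule. |
| initialization | `pca_plane` | — | Deterministic: the codebook spans the plane of the two leading principal components, interpolated over the grid. `random` exists for robustness studies. |
| spot quantile q | 0.98 | — | Candidate tiles are those at or above the q-quantile of node values. 0.98 of a 60 × 60 map flags the top ~72 tiles; on small grids q must be lowered so that (1−q)·K clears `min_size`. |
| spot `min_size` | 3 | nodes | Suppresses single-tile noise components. |
| connectivity | 8 | — | Diagonal adjacency; spots are visually contiguous regions. |
| top-list lengths | 100 / 1000 / 3600 | features | The customary short / intermediate / full-map filter lengths. |
| FDR thresholds | 0.005 / 0.01 / 0.05 | — | Local-FDR cutoffs offered by the filtering stage. |
| entropy ε | 1e-12 | — | Stabilizer added to the shifted entropy weights (below). |
| second-level grid | side `ceil(sqrt(2M))` | tiles | Smallest square with ≥ 2 tiles per sample, honoring K₂ > M so the metasample map has empty space to separate samples. |

## Numerical and design choices

**BMU ties.** Exact ties (squared distances within 1e-9) break to the
lowest node index — deterministic and testable. Gene presentation order is
a seeded permutation, reshuffled per epoch; identical input + seed gives a
bit-identical map.

**Spot segmentation** is not specified by the method's source beyond its
visual reading; the package uses quantile thresholding + connected
components per sample, and defines *global* spots as the connected support
of the over-/under-summary maps (a summary node is nonzero exactly when it
belonged to at least one per-sample spot, so no second threshold is
imposed on the master map). On the bundled fixture this recovers the four
planted modules with ≥ 98% gene precision and recall.

**Entropy weights.** The specificity entropy is defined on "logged
expression" of C clusters, which can be negative; probabilities need
nonnegative weights. The package shifts by the per-sample minimum,
`w_c = max(e_c − min_c e_c, 0) + ε`, then normalizes. Consequences: the
least-expressed cluster always gets weight ≈ ε (conservative toward low
entropy), and an all-equal sample degenerates to the uniform distribution,
H = 1, with a warning — the documented convention.

**F-score.** The benchmark is the distance-based one-way ANOVA ratio
(pseudo-F): with squared pairwise Euclidean distances between samples,
$F = \frac{(SST - SSW)/(k-1)}{SSW/(n-k)}$. An alternative literal reading —
the variance of the between-category distance *values* over the variance
of the within-category distance values — was evaluated and rejected: on
planted-module data it inverts the expected metagene-versus-single-gene
ordering, because tight within-category gene-level distances have tiny
variance regardless of separation. The pseudo-F matches the
"inter-to-intra cluster ratio of the Euclidean distances" reading, is
scale- and rotation-invariant, and is ~1 under label permutation.

**IC variance fraction.** The per-category share of the ICA plot is
`100 · (var IC1 + var IC2)_category / Σ_ref (var IC1 + var IC2)_category`,
with the denominator summing each reference category's own within-category
variance. The alternative (variance within the pooled union) conflates
within-category spread with between-category separation and does not give
equal shares to equal-variance categories.

**Shrinkage-t / local FDR.** The per-gene score is
`max_m |Δe_{g,m} / (s*_{g,m} + s0)|` where the noise SD is estimated
leave-one-out — the profile SD with the tested sample removed — then
shrunk toward the median leave-one-out variance (intensity from the
variance of the per-gene variance estimates) and stabilized by
`s0 = 0.01 · median SD`. Leave-one-out matters: with the plain profile SD
a single strongly differential sample inflates its own noise estimate and
caps its |t| at $(M-1)/\sqrt{M}$ no matter how large the effect is. The
two-sided p-value uses the t reference with M−2 df and the
order-statistic correction $p = 1-(1-p_\text{single})^M$ for taking the
max over M samples (without it the null p-values pile up near zero and no
FDR calibration is possible). The local FDR is the standard two-component
mixture: π₀ estimated from the p > 0.5 half, the marginal density from
the Grenander (least-concave-majorant) estimator — equal-width histogram
bins cannot resolve signal p-values of order 1e-6 — and
`fdr(p) = min(1, π0 / f(p))`, monotone in p by construction.

**Hypergeometric tail** is computed through the log-space CDF
(`stats::phyper`), exact for all argument sizes; log₁₀ p is floored at
−300 for rendering. The universe is the set of genes mapped on the SOM:
the draw producing a minicluster is from mapped genes, not from a larger
annotation universe. Raw p-values are reported (per-tile maps and spot
lists); a Benjamini–Hochberg column is attached to spot lists as a clearly
labeled extension.

**Portrait contrasts.** `logFC` is the codebook column itself and the only
contrast any downstream statistic consumes. `WAD` multiplies each node by
its min–max position within the sample (accentuating strong
overexpression); `loglogFC` applies a sign-preserving
`log10(1 + |v|/median|v|)` (expanding weak-to-moderate signal). Both are
declared stand-ins for rendering only: the original method names these
scales but defines them in supplementary material not part of this
package's sources.

**Degenerate inputs.** Flat portraits degrade WAD to zeros with a warning;
all-equal node values yield zero spots with a warning; empty metagenes are
excluded from metagene ranking, render grey, and have undefined (NA)
compression factor and FDR; a rank-deficient covariance falls back from
`pca_plane` to seeded random initialization with a warning.

## What the synthetic generator emulates — and what it does not

`generate_planted_modules()` builds log₁₀-scale data: background cells
i.i.d. Normal(b = 2, σ = 0.2), plus `n_modules` disjoint blocks of
`genes_per_module` genes receiving +δ (δ = 1) in their module's disjoint
block of active samples (optionally −δ/2 elsewhere, mimicking the
anti-correlation of tissue-specific genes). The defaults — 2,000 × 24,
4 modules × 100 genes × 6 samples, δ/σ = 5 — are the package's stated
test world: strong, clean, block-structured modules that train a 20 × 20
map in seconds.

It deliberately does **not** emulate: probe-level measurement noise or
platform calibration, correlated background (housekeeping covariation,
batch effects), partially overlapping or nested modules, unbalanced sample
groups, or count-distribution mean–variance coupling. Green tests
therefore establish algorithmic correctness and recovery under clean
planted structure, not robustness to real-data pathologies; conversely a
method change that breaks them has broken something fundamental.

Two consequences worth knowing when reading the test suite: background
miniclusters average a handful of pure-noise genes, so their
centroid-to-codebook correlation is moderate (median ≈ 0.7) while module
miniclusters track their centroids at r > 0.9; and discrete hypergeometric
tests on ~5-gene miniclusters are conservative under the null (~1% of
tiles reach p < 0.05), which the calibration tests assert one-sidedly.

## Known limitations

* Hexagonal lattices, toroidal topology and batch-SOM are out of scope
  (the planar rectangular map keeps corner spots meaningful).
* The training loop is pure R; a 60 × 60 map on ~22k genes takes minutes,
  not seconds. The pipeline default grid is therefore 20.
* No multiple-testing correction is applied to per-tile maps (raw log p,
  as the portraits are read visually); spot lists carry an optional BH
  column.
* Gene identifiers are matched by exact string after whitespace trimming;
  probe-to-symbol mapping is upstream curation.
* The second-level SOM uses full K-vectors per sample; a spot-reduced
  variant is not implemented.
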