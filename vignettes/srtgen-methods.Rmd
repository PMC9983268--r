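---
title: "Simulating spatial transcriptomics counts: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spatial transcriptomics counts: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtgen)
```

## The generative model

Spatially resolved transcriptomics (SRT) measures transcript or UMI counts
of many genes at known 2-D tissue positions — array spots in capture-based
platforms, single cells in imaging-based platforms. `srtgen` treats each
gene independently and decomposes simulation into two orthogonal problems:
*what count distribution* a gene follows across locations, and *where on
the tissue* the large and small counts sit.

### Count distributions

Each gene's counts across locations are modelled by one of four families:

| family  | parameters | variance | zeros |
|---------|-----------|----------|-------|
| Poisson | mean μ | μ | sampling only |
| ZIP | μ, π₀ | — | sampling + structural |
| NB | μ, φ | μ + φμ² | sampling only |
| ZINB | μ, φ, π₀ | — | sampling + structural |

The NB is parameterised by its mean and an overdispersion φ = 1/size, so
φ → 0 recovers the Poisson and the variance inflation is explicit. The
zero-inflated families mix a structural-zero point mass of probability π₀
into the count component; their marginal mean is (1 − π₀)μ. Fits maximise
the observed-data log-likelihood: Poisson and the NB mean have closed
forms (the sample mean), the NB overdispersion is a 1-D profile
maximisation, and ZIP/ZINB are maximised numerically (Nelder–Mead) from
multiple starts — a moment-matched start plus π₀ ∈ {0.1, 0.5}. Likelihoods
are evaluated on the tabulated unique count values with multiplicity
weights, which makes a 4-family fit of a sparse gene essentially free.
Model choice is by AIC = 2k − 2ℓ; ties within 1e-9 break toward parsimony
(Poisson, then NB, then ZIP, then ZINB — NB before ZIP at equal k because
overdispersion is the more common mechanism for excess zeros in this data
type). An all-zero gene short-circuits to Poisson with μ = 0: no family is
identifiable there, and the zero-inflated likelihoods are flat along a
μ–π₀ ridge.

Numerical guards: φ is kept above 1e-8 and π₀ below 1 − 1e-8 during
optimisation; boundary fits are legitimate and reported as-is. A
zero-inflated family fitted to data without zeros fixes π₀ = 0 (the
likelihood is flat in π₀ there). After optimisation the nested special
cases (π₀ = 0; for ZINB also the φ → 0 ZIP limit) are evaluated and adopted
whenever the interior solution is worse, so the likelihood-nesting
inequalities hold by construction up to optimiser tolerance.

### Spatial pattern by rank assignment

Sampling fresh counts from the fitted model and placing them at the
location whose *reference expression has the same rank* reproduces the
reference's spatial ordering without assuming any parametric spatial
model. With identical locations and a tie-free reference this makes the
per-gene Spearman correlation between reference and synthetic expression
exactly 1 (exactness requires the synthetic draw to be tie-free as well;
ties in either vector are averaged by the rank transform and cap the
correlation just below 1). Reference ties are broken by a seeded uniform
permutation within the tied block — a coordinate-independent rule, so tie
handling cannot fabricate spatial structure.

When the synthetic data sit on *new* locations, ranking needs reference
expression at positions that were never measured. For each new location a
count is sampled uniformly (with replacement) from its k = 3 nearest
reference locations, per gene; this pseudo-reference is used *only for
ranking*, while model fitting always uses the original measured counts —
keeping the inference step and the placement step cleanly separated. In
domain-specific simulations the pseudo-reference is imputed within each
domain from that domain's reference locations only, so expression never
leaks across a domain boundary.

### Tissue vs domain simulations

`simulate_tissue()` fits and ranks across all locations; the synthetic
tissue preserves global patterns but smooths domain contrasts.
`simulate_domains()` repeats fitting, sampling and ranking independently
within each labelled domain, which sharpens between-domain contrast — the
easier regime for clustering benchmarks. Both modes accept precomputed fit
tables (`fit_genes()`), which the experimental-design generators reuse so
that a design grid refits nothing.

## Geometry

The tissue outline is estimated by a concave hull: starting from the
convex hull, boundary edges are dug inward toward nearby interior points,
longest edge first. An edge of length L is dug toward the interior point p
nearest to it only when L > c·d(p, edge) (c is the `concavity` parameter,
default 2), when the triangle removed contains no other input point, and
when the polygon stays simple. The empty-triangle condition guarantees
every input point remains inside or on the hull; the threshold makes the
hull converge to the convex hull as c grows, and processing edges
longest-first makes the enclosed area monotone in c in practice. The
parameter is deliberately exposed as a plain dig-threshold multiplier with
a documented default rather than being matched to any specific published
hull implementation, whose parameter scales differ.

Grid locations are placed on a square lattice whose pitch is solved by
bisection until the interior point count is within ±10% of the request
(ties resolved toward more points); random locations are rejection-sampled
uniformly. Domain labels transfer to new locations by Boyer–Moore majority
vote over the k = 3 Euclidean nearest reference locations; the vote only
guarantees a winner when a strict majority exists, and with k = 3 and three
distinct neighbour labels there is none, so the nearest neighbour's label
is the deterministic fallback. kNN distance ties break toward the lowest
location index, for determinism.

Region redesign maps one region's pattern onto another through an affine
transform. Hulls of different regions have different vertex counts, so no
vertex correspondence exists; the transform instead aligns each polygon's
*anchor frame* — centroid, principal axes of the vertex cloud (signs fixed
to avoid reflection; near-isotropic shapes fall back to the coordinate
axes), and per-axis extents. Source locations are projected into the
target, carry their counts, and the usual pseudo-reference/ranking
machinery runs with the projected locations as reference.

## Reference-free designs

Primitive shapes are circles (regular polygons, ≥ 16 vertices), squares,
and annuli. An annulus is represented as a *single simple polygon* via a
narrow angular slit joining the outer and inner rings (slit half-width
1e-4 of a vertex step), so even-odd containment excludes the hole while
the geometry stack only ever deals with simple polygons; the area error is
of the order of the slit and the discretisation. Domains may be given as a
labelling function or as named sub-shapes applied by containment, listed
outermost first; interior points of a later (inner) shape override earlier
labels, while boundary points do not (overriding requires strict
containment), so the outermost label wins boundary ties. Per-domain fold
changes multiply the count-component mean μ only — "mean fold change"
leaves φ and π₀ untouched — and counts are permuted uniformly within each
domain, so reference-free genes carry domain-level contrasts but no
within-domain spatial structure (continuous gradients are deliberately out
of scope here).

## Benchmark-design generators

**SE designs** draw every gene from NB with a shared dispersion; SE genes
change only their in-domain mean by a fold. Defaults follow the two
canonical regimes: a sparse array-capture regime (baseline μ = 0.03,
φ = 0.3, folds 5/10 up and 1/5 1/10 down) and a moderate
single-cell-resolution regime (μ = 0.4, φ = 0.35, folds 3/4 and their
inverses); the folds vector is split equally over the SE genes, so the
default 100 SE genes give 50 up- and 50 down-regulated. The shared
dispersion is an explicit input rather than being estimated from a
reference by one particular estimator, since reasonable estimators (pooled
likelihood, median of per-gene fits) differ and the design only needs a
fixed value.

**Clustering design grids** vary (I) total sequencing depth at fixed
locations — implemented by multiplying every fitted μ by the depth factor,
which keeps each selected family closed under scaling, rather than by
binomial thinning of sampled counts (thinning changes the zero structure
of zero-inflated fits and is not obviously equivalent); (II) location
number at fixed total depth (per-location mean rescaled by n_ref/n_new);
(III) the cross-product at fixed per-location depth. Fits are reused
across the grid; refitting per cell would conflate estimation noise with
the design variable.

**CCC designs** build a single-cell-resolution dataset: uniform cell
positions inside an estimated outline, four equal-count regions along the
first principal axis of the position cloud ("equal-sized" is realised
exactly as equal counts; the source text fixes no region geometry), cell
types drawn per region from a rotated composition vector, and a pool of
2000 cells per type whose expression is NB — shared parameters in the
homogeneous mode, synthetic type-specific parameters in the heterogeneous
mode (a labelled synthetic stand-in for type profiles estimated from a
real single-cell reference). Ligand–receptor pairs are assigned uniformly
to the 16 *ordered* type pairs (self-pairs included — 4 types give exactly
16 ordered combinations). For every A-cell with a B-cell among its 4
nearest neighbours, the *ligand* gene's count in the A-cell is multiplied
by the fold and rounded; the receptor side is left untouched, which is the
literal reading of the design, and a cell is boosted at most once per gene
even when a ligand participates in several assigned pairs, so boosts never
compound. Pool cells are sampled onto positions with replacement only if a
type's demand exceeds its pool. The bundled L-R resource
(`make_lr_pairs()`) is synthetic by construction — 930 pairs over 445
ligand and 471 receptor identifiers spanning 691 distinct genes — and is
clearly labelled as such; it reproduces the combinatorics of a curated
resource, not its biology.

## Fidelity metrics

Gene-wise mean, variance (n − 1 denominator), coefficient of variation
(sd/mean, reported missing when the mean is zero and dropped from KS
comparisons with the drop count logged), and zero proportion; location-wise
zero proportion and library size. Distributions are compared by two-sample
Kolmogorov–Smirnov tests (asymptotic p-values). Spatial pattern agreement
is summarised by per-gene Moran's I, computed on raw counts by default
(normalisation is exposed to the caller by passing transformed values); the
neighbourhood is binary symmetrised kNN with k = 5, not row-standardised —
a definition that behaves consistently on both grid and random layouts —
and is configurable, including a precomputed weight matrix. Moran's I of a
constant gene is undefined and reported missing. The statistic is only
descriptive here; no significance testing is attached.

## Seeds and reproducibility

Every stochastic step draws from a substream seed derived by hashing the
user seed with a fixed stage index (and gene/domain/replicate indices), so
adding genes or stages never perturbs draws in earlier substreams, and
identical inputs plus seed reproduce any output bit-for-bit. All derived
seeds stay below 2³¹.

## What the synthetic fixtures do and do not show

The bundled reference generator (`make_reference_fixture()`) draws
per-gene parameters from documented ranges (log-uniform means defaulting
to a sparse regime with zero fraction above 0.8, as in array-capture
tissue data; uniform φ and π₀) and implants contiguous layered domains
with fold-change genes. It emulates the *statistical* features the
simulator consumes — marginal count behaviour and domain-level structure —
but not gene–gene correlation, spatial gradients within domains,
platform-specific artefacts, or segmentation noise. Tests passing on these
fixtures therefore validate the machinery (fitting, selection, ranking,
geometry, designs), not the claim that any particular real tissue is fully
captured. Since each gene is simulated independently, gene–gene
correlation is *by design* absent from synthetic data — a known limitation
shared with the per-gene modelling approach generally, and the reason
co-expression analyses should not be benchmarked with this generator.

## Problem sizes used by the test-suite

The statistical checks run at sizes chosen to make their error bands
meaningful while staying desk-scale: distribution preservation on a
1000-gene × 2000-location NB fixture over 10 simulation seeds; Moran's I
concordance on 500 genes (50 strongly layered, fold 8, means 0.3–3) at
1000 locations; oracle agreement of the ML fits on 20 vectors per family
at n = 5000 against a two-stage grid search; SE folds at 673 locations and
the CCC composition check at the canonical 5000 positions. Spearman
exactness uses high-mean Poisson references (μ = 1e9, 30 locations, with
duplicate-carrying genes redrawn) because exact rank agreement is only
defined for tie-free vectors.

## Known limitations

- Single simple polygons only: tissues with holes or disjoint islands are
  not modelled (the annulus slit is the one sanctioned exception).
- No gene–gene dependence, no within-domain gradients in reference-free
  mode, no cell-type deconvolution layer.
- The concave hull is a heuristic; its area monotonicity in the concavity
  parameter is an empirical property of the longest-edge-first rule, not a
  theorem.
- Depth variation by mean scaling is one of several defensible mechanisms;
  count thinning would yield slightly different zero statistics for
  zero-inflated genes.
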