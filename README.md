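# srtgen

Simulation of spatially resolved transcriptomics (SRT) count data that
preserves both the count-distribution properties and the per-gene spatial
expression patterns of a reference dataset.

## The problem

Methods for SRT data — spatial clustering, spatially variable gene
detection, cell–cell communication inference — need synthetic data with a
known ground truth to be evaluated fairly. Single-cell RNA-seq simulators
can reproduce the marginal count properties of a gene, but they carry no
notion of *where* a count was measured, so the layered and regional
structure of tissue expression is lost. `srtgen` generates gene × location
count matrices that keep both.

## The method

**Reference-based simulation** works in three steps, given a reference
count matrix `Y` (genes × locations) with coordinates and optional spatial
domain labels:

1. **Locations.** Reuse the reference coordinates, or estimate the tissue
   outline with a concave hull and place a user-specified number of fresh
   locations inside it (square grid, as in array-capture platforms, or a
   uniform random point process, as in imaging platforms). Domain labels
   transfer to new locations by majority vote over the k = 3 nearest
   reference locations.
2. **Count models.** For each gene (per tissue, or per domain), fit four
   count families by maximum likelihood — Poisson, zero-inflated Poisson
   (ZIP), negative binomial (NB; mean μ, overdispersion φ with variance
   μ + φμ²), and zero-inflated NB (ZINB, structural-zero probability π₀) —
   and keep the fit with the lowest AIC = 2k − 2ℓ. Fresh counts are then
   sampled from the selected model.
3. **Rank assignment.** Place the i-th largest sampled count at the
   location with the i-th largest reference expression, so the synthetic
   gene reproduces the reference's spatial ordering. For fresh locations, a
   pseudo-reference is first imputed by sampling counts from each new
   location's k nearest reference neighbours. A region's pattern can also
   be *redesigned* by affinely projecting another region's locations onto
   it and ranking against the projected counts.

**Reference-free simulation** realises user-designed tissues: primitive or
custom shapes, grid/random locations, geometric domains, a count model per
gene, and per-domain mean fold changes, with counts allocated at random
within each domain.

Fidelity is evaluated with four gene-wise metrics (mean, variance,
coefficient of variation, zero proportion), two location-wise metrics (zero
proportion, library size), two-sample Kolmogorov–Smirnov tests of each
metric distribution, and per-gene Moran's I for spatial-pattern
concordance. Benchmark-design generators produce spatially variable gene
(SE) null/alternative datasets, sequencing-depth/location-number design
grids, and single-cell-resolution ligand–receptor (L-R) communication
datasets with adjacency-driven signal — each with a truth table.

## Worked example

```r
library(srtgen)

# a synthetic reference with known ground truth: 200 genes on 600 random
# locations, 4 layered domains, 30 genes with a 6-fold domain pattern
fx <- make_reference_fixture(n_genes = 200, n_locations = 600,
                             layout = "random", n_domains = 4,
                             pattern = "layered", n_pattern = 30,
                             pattern_fold = 6, mu_range = c(0.05, 1),
                             seed = 1)
fx$data
#> <srt_data> 200 genes x 600 locations
#> domains: domain_1 (150), domain_2 (150), domain_3 (150), domain_4 (150)
#> coordinates: x in [0.00249, 0.997], y in [0.001, 1]

sim <- simulate_tissue(fx$data, seed = 2)   # fit, select, sample, rank-assign
dplyr::count(tidy(sim), family)             # which families won the AIC selection
#>   family      n
#> 1 nb        117
#> 2 poisson    44
#> 3 zinb        2
#> 4 zip        37

report <- fidelity_report(fx$data, sim$data)
report
#> KS comparisons (reference vs synthetic):
#>              metric statistic p_value n_ref n_syn
#>                mean     0.030   1.000   200   200
#>            variance     0.035   1.000   200   200
#>                  cv     0.055   0.923   200   200
#>      gene_zero_prop     0.030   1.000   200   200
#>  location_zero_prop     0.025   0.992   600   600
#>        library_size     0.045   0.578   600   600
#> Moran's I concordance (Pearson r, knn (k=5)): 0.989
```

All six metric distributions are statistically indistinguishable from the
reference (every KS p-value above 0.05), and the per-gene Moran's I values
of the synthetic data track the reference's almost perfectly — the layered
genes stay layered, the unstructured genes stay unstructured.
`autoplot(report)` draws the violin panels and the Moran's I scatter;
`plot_gene_spatial(sim$data, "gene_0001")` maps a single gene.

A command-line interface wrapping the same functions ships in
`inst/cli/srtgen.R` (subcommands `fit`, `simulate`, `free`, `metrics`,
`design-se`, `design-ccc`, `design-clustering`), writing a provenance JSON
with every run.

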