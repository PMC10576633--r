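---
title: "tapomics: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tapomics: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapomics)
```

## The data and the problem

Droplet-based targeted single-cell multiomics platforms profile, for every
cell of one biological sample, three aligned read-outs over a predefined
amplicon panel: DNA variant calls (allele frequency `AF` in percent,
genotype code `NGT` — 0 wild-type, 1 heterozygous, 2 homozygous alternate,
3 missing — quality `GQ`, depth `DP`), CNV amplicon read counts, and
antibody-capture protein counts. The three assays share one set of cell
barcodes, delivered in a multi-assay HDF5 file. The analytical goal is to
resolve the clonal structure of a heterogeneous sample — which cells carry
which genotype — and then ask how copy number and surface-protein
expression differ between those clones.

`tapomics` covers the downstream path: reading and validating the HDF5
container, QC-filtering the variant calls, clustering cells into clones on
their VAF profiles, estimating per-amplicon ploidy against a diploid
reference clone, CLR-normalizing and testing protein expression, and a
synthetic generator that produces the whole structure with known ground
truth.

## The sample container

A `MultiomicSample` holds the three assays plus clone labels and
processing-status flags. The assays may disagree on barcodes on disk
(droplets drop out of individual assays), but a clone label derived from
DNA must index the same cell's row in every assay, so a single canonical
cell order is mandatory. `build_sample()` therefore intersects the three
barcode sets and sorts the intersection lexicographically — a deterministic
order independent of on-disk order — logging a per-assay count of dropped
barcodes. Erroring on ragged barcode sets instead would make most real
files unreadable.

Clone labels use 0 for unassigned/noise cells and positive integers for
clones, renumbered `1..K` by decreasing clone size (ties: smaller original
label first). "Clone 1 is the largest clone" is then a stable,
interpretable convention independent of clustering internals.

## Variant-call QC

A call is *valid* when `NGT != 3`, `DP >= min_depth` (default 10),
`GQ >= min_gq` (default 30), and — for mutant calls only — `AF >=
min_af_mutated` (default 20%). Filtering is cells-then-variants: cells with
fewer than `cell_min_valid_fraction` (default 0.5) valid calls are removed
from all three assays first, so that hopeless cells cannot doom otherwise
usable variants; then variants need `variant_min_valid_fraction` (default
0.5) valid calls and a mutant fraction of at least
`variant_min_mutated_fraction` (default 1%) among their valid calls. The
defaults mirror common practice for targeted single-cell DNA panels and
are all overridable; the exact defaults used upstream of the published
counts for the public four-cell-line dataset are not published, so
reproducing those counts exactly may require tuning against that file.

Invalid calls that survive filtering are recorded in a validity mask and
treated as missing downstream rather than zeroed — zero AF is a biological
genotype, absence of evidence is not.

## Clone identification

Cells are clustered with DBSCAN on `AF / 100` (Euclidean metric), so
coordinates live in `[0, 1]` and genotype classes sit 0.5 apart per
variant. DBSCAN needs no preset clone count and labels low-density cells as
noise (label 0); noise cells are excluded from all clone-level statistics
(ploidy means, signature tests) to keep clone summaries uncontaminated.
`min_points` defaults to 10 (the point itself counted, the usual
convention). When `epsilon` is not given it is set to the maximum-curvature
knee of the sorted `min_points`-nearest-neighbour distance curve — the
point of maximum perpendicular distance to the chord joining the curve's
endpoints — and logged, because a named algorithm with an unlogged
auto-chosen radius is not reproducible.

Masked (invalid) calls are imputed for clustering with the per-variant mean
over valid calls. This estimator pools cells across clones, so a cell with
several masked calls is displaced toward the grand centroid and may be
labelled noise; that is visible in the synthetic world as a noise fraction
comparable to the per-cell probability of carrying masked calls. A
clone-aware imputation would need the labels being estimated — we prefer
the simple, deterministic choice and the honest noise label.

## CNV normalization and ploidy

Raw amplicon counts `c(i, j)` mix three signals: per-droplet depth,
per-amplicon primer efficiency, and the copy number of interest.
`normalize_cnv()` removes the first two in a fixed order:

1. row step — `r(i,j) = c(i,j) / T(i) * median(T)`, with `T(i)` the cell's
   total; cells with `T(i) = 0` are dropped (from all assays) with a
   warning;
2. column step — `n(i,j) = r(i,j) / median_i r(i,j)`; amplicons with zero
   median are dropped with a warning.

Medians rather than means are used so that one large aneuploid clone does
not drag the scaling. `calculate_ploidy()` then anchors the scale: a
designated reference clone (at least `min_reference_cells = 10` cells,
fewer giving too noisy an anchor) is declared diploid, `mu(j)` is the
reference mean of amplicon `j`, and `p(i,j) = 2 n(i,j) / mu(j)`.
Clone-level ploidy is the mean of cell ploidies within each clone, which
makes the reference clone's row identically 2 — an algebraic identity the
test suite asserts to 1e-9 on arbitrary random inputs, and the package's
acceptance target.

Two properties worth knowing:

* the column step cancels exactly in the ploidy ratio, so ploidy is driven
  by the row step and the reference anchor;
* because the row step divides by the cell total, ploidy is identifiable
  only up to each clone's average genome dosage: a clone whose mean copy
  number across the panel (weighted by amplicon efficiency) is `m` has all
  its ploidies scaled by `2/m`. For clones whose aberrations roughly
  balance (mean dosage ≈ 2) the estimates are unbiased, and the synthetic
  recovery tests use such profiles; strongly hyperdiploid clones will read
  systematically low. This is a known limitation of total-count
  normalization on targeted panels, not of this implementation.

## Protein normalization, embedding, and signatures

Antibody counts are compositional, so `clr_normalize()` applies the
centred log-ratio per cell across proteins with a +1 pseudocount on the
natural-log scale: `y(i,k) = ln(c(i,k)+1) − mean_m ln(c(i,m)+1)` — the
standard convention for antibody-derived tag counts. Every CLR row sums to
zero exactly; with the pseudocount the transform is *not* invariant to
per-cell count scaling (that invariance only holds in the pseudocount-free
limit), which is documented rather than asserted.

`reduce_dim()` offers UMAP (default, seed 42 recorded on the object),
t-SNE, and PCA. PCA is fully deterministic; component signs are fixed so
the largest-magnitude loading of each component is positive, making test
comparisons against an independent eigendecomposition well-defined.

`find_signature()` contrasts one clone against all other labelled cells,
per protein, with a two-sided Welch t-test — clone sizes and variances
differ grossly in mixtures, so pooled variance is not assumed (the choice
is deliberate and the Welch statistic is computed in closed form, with
`stats::t.test` serving as an independent oracle in the tests). Zero-variance
degeneracies resolve to p = 1 when the means agree and p = 0 otherwise.
P-values are BH-adjusted across the proteins of the one call — matching
"sorted by adjusted p-value for one target clone" semantics — and the
table is sorted by adjusted p, ties broken by raw p, then protein id.

## The synthetic world

`synthetic_config()` states a small, explicit world: per cell of clone
*g*, AF is Gaussian around the genotype centres 0/50/100 (sd 2 percent,
clipped to [0, 100]); DP is Poisson around `mean_depth = 80` times a
gamma per-cell factor (shape 10); GQ is constantly 99 for non-dropout
calls; a `dropout_rate = 0.01` fraction of calls is set missing (NGT 3,
GQ 0, DP 0). CNV counts are Poisson with rate `cnv_mean_depth = 60` ×
cell factor × `cn/2` × amplicon factor, the two factors log-normal
(sd 0.15) — exactly the row- and column-wise variation the normalization
claims to remove, which is what makes it testable. Protein counts are
negative binomial (size 5, typical antibody overdispersion) around clone
means. One master seed drives three per-assay sub-seeds, so extending one
assay's draws never perturbs another's.

The default 3-clone mixture (150/100/50 cells, 30 variants, 20 amplicons,
8 proteins) has genotype profiles ≥ 0.4 apart per differing coordinate in
scaled-VAF space, copy-number profiles with per-clone mean dosage 2, and
one marker protein per clone. What a green test on this world establishes
is that the estimators recover parameters *of this model*: clean clusters,
no doublets, no ambient antibody background, no GC or fragment-length
effects, independent calls. Real data violate all of these to some degree;
the public-dataset checks exist precisely because the synthetic world
cannot stand in for them.

Numerical conventions collected in one place: clipped-Gaussian AF has mean
`100 − sd·φ(0)` at a homozygous centre (≈ 99.2 at sd 2), and the generator
tests assert that closed form, not the nominal centre; DBSCAN ties in
clone size are broken by discovery order, so order-invariance is asserted
at the partition level; the knee estimator falls back to a 1e-6 floor for
degenerate (all-identical) inputs; filtering that removes every cell or
every variant is a fatal error naming the responsible thresholds.

## Command line

`exec/tapomics` exposes `summary`, `filter`, `clones`, `cnv`, `protein`,
`signature`, `simulate` and `run` (the full chain). `run` writes the
filtered HDF5, the filter report, labels, clone ploidy, embedding and
signature tables as TSV, plus a log capturing every applied default and
every auto-chosen parameter, so a run is reproducible from its log alone.
Configuration files are JSON.

## Known limitations

* Ploidy is relative to the reference clone and to mean genome dosage (see
  above); no segmentation or allele-specific copy number.
* The annotation provider bundled with the package is a small synthetic
  lookup table; the vendor-API provider is an extension point, not
  implemented.
* Published cell/variant/clone counts for the public four-cell-line
  dataset depend on unpublished upstream defaults; the package asserts
  them when that file is locally available and cannot do so offline.
* One sample per container; no multi-sample integration.
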