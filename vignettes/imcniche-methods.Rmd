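---
title: "imcniche: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{imcniche: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imcniche)
```

This vignette is the package's account of its own methods: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic generator does and does not emulate, and where genuinely
open design choices were resolved. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Data model and conventions

The central object is the **cell table**: one row per segmented cell with
coordinates in µm, raw and/or normalised marker intensities, a population
label, a parent group, and ROI/case/region/treatment metadata. Images are
matrices indexed `[row, col]` with the origin at the top-left; pixel
`(r, c)` has its centre at `(c - 0.5, r - 0.5)` µm and y increases downward;
pixel pitch is 1 µm. This convention is stated once and used everywhere
(rendering, quantification, Jaccard QC).

All randomness flows from one root seed via named substreams
(`substream_seed(seed, "placement:ROI1")`, …), so stages can be re-run
independently while a fixed seed reproduces every output byte for byte.

## The synthetic tissue generator

The generator emulates the conditions the analysis is designed for:
1000 × 1000 µm ROIs; ~20 populations across Schwann / myeloid / lymphoid /
vascular / other parent groups; **Antoni A-like** ROIs that are dense
(~2700 cells/mm² at scale 1) and organised — Schwann populations as Thomas
cluster processes, vascular populations and hypoxic perivascular neutrophils
confined to 30 µm halos around vessel polylines, and a planted
TAM × CD8-TEMRA aggregate realised as shared Thomas parents, which by
construction spatially excludes the independently clustered Schwann cells —
and **Antoni B-like** ROIs that are sparse (~1100 cells/mm²), interspersed
(CSR), with a planted CD8-TEMRA × PD-L1⁺-Schwann mixing pair.

Key defaults, chosen once as the study conditions:

* placement: Thomas parents at `density / mean_offspring` per mm²,
  `mean_offspring = 25`, `sigma = 30 µm` for Schwann clusters; planted pairs
  use `kappa = 8-10 /mm²`, `sigma = 15-20 µm`, strength (fraction of cells
  attached to shared parents) 0.6-0.7;
* intensities: per-population mean profiles with multiplicative log-normal
  noise (`sdlog = 0.3`), canonical markers at 25× the background level;
* batch effects: log-normal multipliers per (case, marker), `sdlog = 0.25` —
  the intensity-scale artefact that batch-balanced graph construction
  targets;
* expression: negative-binomial counts (`size = 2`, baseline mean 2) with
  planted ligand/receptor folds (default 8) in sender/receiver populations.

Shared-parent co-clustering was chosen over displacement-based coupling
because it guarantees a positive cross-PCF at short range with a single
interpretable knob (the attached fraction). Rendering uses hard discs — no
point-spread blur — precisely so that quantification round-trips are exact
and test failures indict the code, not the optics. The generator does **not**
emulate acquisition noise physics, hot pixels, denoising artefacts,
segmentation errors (beyond the explicit mask-perturbation operation), or the
marker cross-over between intertwined cell types seen in real tissue; passing
tests therefore validate the statistical machinery, not robustness to those
effects.

## Quantification

The mask is expanded `expansion_px` times (default 1) with the 8-connected
structuring element. The underlying protocol names only "one pixel
expansion"; the square element and the contested-pixel rule (nearest nuclear
centroid, ties to the lower label) are this package's documented choices,
matching common IMC practice. Per-marker means are taken over the expanded
region. Mass conservation (Σ area × mean ≤ total image signal) and
label-renumbering invariance are asserted in tests. Jaccard QC samples 50
cells per ROI without replacement (all cells, logged, when fewer exist) and
matches objects by maximal pixel overlap; an unmatched cell scores 0 and is
flagged rather than dropped.

## Phenotyping

Percentile normalisation divides each marker by its q-th percentile
(q = 99.9) using type-7 linear interpolation between order statistics —
stated because implementations differ — and clips to [0, 1]; clipping keeps
all markers on a common scale for distance computations since the protocol is
silent about values above the percentile. A normalised table carries a
`normalized` attribute and passes through unchanged on re-normalisation;
stored divisors reproduce the transform on new raw data.

The batch-balanced graph takes each cell's `k_per_batch` (default 3) nearest
neighbours **within every case separately**; the union, weighted
`1/(1 + d)`, is clustered by Leiden modularity optimisation. The original
resolutions and k are not recoverable from the protocol; the defaults
(coarse 1.0, fine 1.5) are configuration, not validated against the original
analysis. A practical note measured during development: igraph's modularity
resolution of 1.0 oversplits small, clean toy graphs (hundreds of cells), so
the toy-recovery tests run at resolutions of 0.01-0.05 while pipeline
defaults stay at 1.0/1.5. Parent groups are assigned per coarse cluster by
the highest canonical-marker mean (threshold 0.1, else "Other"); population
annotation is data-driven (YAML-able rules of positive/negative markers at a
0.3 cluster-mean threshold) because the published populations arise from
expert annotation that cannot be hard-coded.

## Cross-PCF and ACN

The estimator is

$$\hat g_{AB}(r_k) = \frac{1}{n_A} \sum_{i \in A}
  \frac{c_i(r_k)}{\hat\rho_B \, a_i(r_k)},$$

with exact annulus ∩ rectangle areas (inclusion-exclusion over signed
quadrant integrals — deterministic, and tested against grid integration to
2·10⁻³ relative error). `gr20` is the [19, 20) µm bin at `dr = 1`: the
summary is named after r = 20 µm but no binning is published, so the final
bin is this package's convention. Without edge correction
`ĝ_AB = ĝ_BA` exactly (asserted); with correction the estimator is unbiased
under CSR (mean gr20 over 200 Poisson ROIs sits in [0.9, 1.1], recomputed by
the acceptance script).

**Significance** permutes population labels among all cells with positions
fixed, two-sided around the CSR value 1:
`p = (1 + #{|perm − 1| ≥ |obs − 1|}) / (n_perm + 1)`. Two properties of this
null deserve explicitness:

* *Discreteness.* At 100 cells/type/mm² the final bin holds ~1.2 cross pairs
  per ROI; gr20 is then so discrete that the (exact) test is deeply
  conservative — its rejection rate under the null is near 0, not α. The
  type-I calibration therefore runs at 400 cells/type/mm², where the
  statistic has resolution and the empirical rate is ~0.04 at α = 0.05.
* *Exchangeability.* The null conditions on positions. If the only cells in
  the ROI are the two co-clustered populations built on the same parents,
  their labels are exchangeable and the test has (correctly) no power;
  detection requires the surrounding tissue context, which the multi-
  population generator provides. Power simulations include a CSR background
  population for this reason.

ACN "contact" is centroid distance ≤ 10 µm (about one cell diameter at IMC
resolution); the protocol never defines contact, and this is the single
implemented definition (configurable radius; mask-adjacency was considered
and not adopted). The ACN permutation null has no natural centre analogous
to 1, so its two-sided p-value is centred at the permutation mean. p-values
are BH-adjusted across pairs within each ROI, and a region-class network
edge requires significance in a configurable fraction of that class's ROIs
(default majority); both per-ROI q-values and consensus fractions are
reported because the original multiplicity handling is unstated. Edge weight
is mean gr20, node size mean abundance.

## Cellular neighbourhoods

The spatial substrate is a Delaunay triangulation trimmed at 30 µm
(configurable) — Delaunay avoids the density-dependent k of a kNN graph, and
the trim removes spurious long edges across sparse regions. Features
concatenate hop-0 markers with mean markers over exact hop shells 1..L
(L = 3 default; empty shells are zero-filled and flagged). GMMs (full
covariance; conjugate-prior regularisation as the variance floor; diagonal
fallback logged if EM still degenerates) are fitted R = 10 times from
randomised k-means initialisations, and K is chosen by FMI stability —
within-K pairwise FMI across repeats by default, with the between-K variant
(`mode = "between"`) available since the upstream tool's exact scheme is not
restated anywhere. Ties go to the smallest K; the final model is the
best-likelihood fit at K*.

A measured limitation: on spatially aggregated features the stability
criterion can *stably* resolve micro-clusters that are artefacts of the
aggregation — cells with empty (zero-padded) shells, and the
degree-dependent variance of shell means — so K* may exceed the planted
number of domains by one or two tiny clusters while the label agreement
(ARI) with the planted truth stays near 1. The acceptance checks reflect
this honestly: K* recovery is asserted on planted Gaussian domains in
feature space, and on spatially planted domains the assertion is label
agreement at the planted K (ARI ≥ 0.8). Users choosing K on real data should
inspect the stability curve rather than trust the argmax blindly.

Proximity enrichment pools graph edges across the ROIs of one region class
(one matrix per class), computes the fraction of edge endpoints leaving CN i
that land on CN j (rows = sender, columns = receiver), and z-scores it
against within-ROI label shuffles. Region-separate CN derivation (Antoni A
and B independently) is the pipeline default; combined mode exists behind
`region_mode = "combined"` and the two are never mixed silently.

## Receptor–ligand analysis

The score is the CellPhoneDB/Squidpy-style mean-of-means; complexes use the
per-cell subunit minimum before averaging. The permutation test shuffles
labels across cells and is one-sided (enrichment). The 5% expressed-fraction
rule is applied to ligand-in-sender AND receptor-in-receiver — the stricter
reading of an ambiguous sentence — with an OR mode behind a flag. BH runs
within each (sender, receiver) combination, matching per-panel presentation;
a global family is a one-line change. Expression input is library-size
normalised log counts; raw counts pass through the same code path.

## Group statistics

Shapiro–Wilk at α = 0.05 gates every comparison and the gate evidence is
returned with the result (the test choice is a pure function of the recorded
normality outcomes). The Welch variant engages at a variance ratio > 4 — the
original switches between plain and Welch t-tests without stating a rule, so
this threshold is ours. Constant groups (normality undefined) fall to the
nonparametric branch and are noted. Three-group comparisons use ANOVA +
Tukey or Kruskal–Wallis + Dunnett-T3-style pairwise tests; the T3 pairwise
tests are Welch t statistics with Welch degrees of freedom under a
Sidak-form studentized-maximum-modulus adjustment, written here because no
installed package provides T3. Case averaging precedes testing to avoid
ROI-level pseudo-replication; ROI-level values are available for diagnostics
only.

## Numerical choices and problem sizes

Degenerate inputs are either explicit errors (empty graphs, < 3 cases per
group, fold ≤ 0, mask/stack shape mismatch) or flagged results (empty
populations in a PCF, zero B cells in an ACN, all-zero markers). Permutation
p-values use the add-one convention and are bit-reproducible from the seed.
The test suite and acceptance script use deliberately modest problem sizes —
200-800 cells per simulated ROI, 200 ROIs for CSR calibration, 500 for
type-I, 100 seeds for spatial power, 10 × 10 GMM fits for K selection, 20
seeds for receptor-ligand recovery, 1000 simulations for the two-group gate
— sizes at which every targeted property is measurable with comfortable
margins on a single CPU in a few minutes.

## Known limitations

Beyond the generator's idealisations listed above: the per-cell expansion is
nearest-centroid rather than geodesic; ACN contact ignores cell shape; the
permutation nulls condition on the observed point pattern and therefore test
label structure, not clustering per se; FMI stability inherits the
micro-cluster behaviour described above; and the phenotyping defaults
(resolutions, k) are unvalidated against the original expert-annotated
populations, which are a non-goal here.
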