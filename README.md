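# imcniche

Spatial single-cell analysis of segmented multiplexed tissue imaging —
imaging mass cytometry (IMC) and comparable ~1 µm/pixel modalities — built
around tissues with contrasting histomorphic niches, such as the dense,
organised **Antoni A** and sparse, loosely organised **Antoni B** regions of
vestibular schwannoma. The package is aimed at analysts who already have
segmented data (a labelled nuclear mask plus a channel stack, or a per-cell
table) and want a tested, reproducible route from pixels to group-level
statistics.

## What it computes

**Quantification.** Nuclear labels are expanded by one pixel (8-connected;
contested pixels go to the nearest nuclear centroid, ties to the lower label)
and per-marker means are taken over the expanded region. Segmentation is
QC'ed with per-cell Jaccard indices `J = |A ∩ M| / |A ∪ M|` against a second
mask (50 sampled cells per ROI).

**Phenotyping.** Marker intensities are normalised to their 99.9th percentile
and clipped to [0, 1]; a batch-balanced kNN graph (k nearest neighbours found
separately within every case) feeds Leiden community detection; coarse
clusters map to parent groups (Schwann / myeloid / lymphoid / vascular) by
canonical-marker means and are re-clustered at finer resolution into named
populations.

**Spatial statistics.** For an ordered population pair (A, B) the cross-pair
correlation function is estimated per 1 µm annulus up to 20 µm,

    ĝ_AB(r_k) = (1/n_A) Σ_{i∈A} c_i(r_k) / (ρ̂_B · a_i(r_k)),

with `c_i` the B-cell count in the annulus, `ρ̂_B = n_B/|W|`, and `a_i` the
**exact** annulus ∩ window area (geometric edge correction). `gr20` is the
value of the [19, 20) µm bin; significance comes from permuting labels with
positions fixed (two-sided around the CSR value 1). Adjacency cell networks
(ACN) count A cells in contact with B cells (centroid distance ≤ 10 µm by
default) and the proportion of B touched by A, with a permutation null,
Benjamini–Hochberg control within ROI, and majority-consensus region
networks weighted by mean gr20.

**Cellular neighbourhoods (CN).** Per-cell features concatenate each cell's
markers with mean marker vectors over hop shells 1..L of a trimmed Delaunay
graph; Gaussian-mixture models are fitted repeatedly and the number of
clusters K is selected by Fowlkes–Mallows (FMI) stability,
`FMI = TP/√((TP+FP)(TP+FN))` over co-clustered pairs. Downstream: CN × type
enrichment, CN abundance, CN–CN proximity z-scores (sender rows, receiver
columns), and normality-gated correlation of CN abundance with clinical
covariates.

**Receptor–ligand scoring.** For a pair table (CellPhoneDB-like), the score
is the mean-of-means `(mean ligand in sender + mean receptor in receiver)/2`
(complexes: per-cell subunit minimum), with a one-sided label-permutation
test, a 5% expressed-fraction filter, BH FDR within each population pair, and
top-20 ranking.

**Group statistics.** Case-averaged comparisons gated by Shapiro–Wilk:
t-test (Welch when the variance ratio exceeds 4) or Mann–Whitney U for two
groups; ANOVA + Tukey or Kruskal–Wallis + Dunnett-T3-style pairwise tests for
three. Integration accounting converts alignment/matching counts to the
reported percentages.

A synthetic tissue generator emulates the study conditions (1000 × 1000 µm
ROIs, ~20 populations in 4 parent groups, Antoni A-like clustered/organised
and Antoni B-like sparse ROIs, perivascular niches, planted co-clustered
pairs, per-case batch effects, negative-binomial expression with planted
ligand–receptor folds) so the entire pipeline is testable without acquired
data.

## Worked example

```r
library(imcniche)

# an Antoni A-like ROI with a planted TAM x CD8 TEMRA aggregate
sp    <- vs_tissue_spec("AntoniA", seed = 42, scale = 0.5)
cells <- generate_roi(sp, roi_id = "caseA_A1", case_id = "caseA")
nrow(cells)
#> [1] 1099

res <- pcf_significance(cells, "TAM_classical", "CD8_TEMRA",
                        n_perm = 999, seed = 1, window = c(1000, 1000))
res$observed
#> cross-PCF TAM_classical -> CD8_TEMRA (n_A = 149, n_B = 44)
#>   gr20 = 4.980 over 20 bins
c(res$p_value, res$direction)
#> [1] "0.042" "enriched"

acn(cells, "TAM_classical", "CD8_TEMRA", contact_radius = 10)
#>          type_a    type_b n_a n_b n_a_touching_b prop_b_touched_by_a flagged
#> 1 TAM_classical CD8_TEMRA 149  44             16           0.2954545   FALSE

match_accounting(731237, 659880, 548455)[c("aligned_pct", "matched_pct")]
#> $aligned_pct
#> [1] 90.24
#> $matched_pct
#> [1] 83.1
```

The planted TAM/T-cell aggregate is detected as a spatial enrichment: the
pair correlation at 20 µm is ~5× the CSR expectation and significant under
the label-permutation null (p = 0.042 at 999 permutations); 16 of 149
classically activated-like TAMs are in contact with a CD8 TEMRA cell and 30%
of CD8 TEMRA cells are touched by a TAM. The accounting call reproduces the
alignment (90.24%) and matching (83.1%) percentages from the integration
counts.

A full staged run (simulate → quantify → phenotype → spatial →
neighbourhoods → lr → stats → report) with CSV/JSON/TIFF/GraphML artefacts
and a checksummed manifest:

```r
run_pipeline(demo_config(), outdir = "out", seed = 1)
```

or from a shell via `inst/scripts/pipeline.R`
(`--config --seed --outdir --region --n-perm --stage`).

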