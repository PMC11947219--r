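# Concrete study conditions: a ~40-marker-panel-inspired 20-population
# schwannoma emulation across Antoni A-like (dense, organised, perivascular
# niches, TAM/T-cell aggregates spatially excluding Schwann cells) and
# Antoni B-like (sparse, interspersed, T cell / PD-L1+ Schwann mixing) ROIs.

VS_MARKERS <- c("S100B", "SOX10", "PanCK", "Vimentin", "PDL1", "CD45",
                "Iba1", "CD68", "CD163", "HLADR", "CD74", "CD14", "CD11b",
                "CD3", "CD4", "CD8a", "CD45RA", "AGTR1", "SMA", "CD31",
                "Ki67", "CD44")

# population, parent group, canonical high markers, Antoni A / B density per mm^2
vs_population_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name                     group    dens_a dens_b high
Schwann_S100B            Schwann   800   300  S100B,SOX10,Vimentin
Schwann_PDL1             Schwann   150    90  S100B,SOX10,PDL1,Vimentin
Schwann_PDL1_prolif      Schwann    80    30  S100B,PDL1,Ki67,Vimentin
Schwann_PanCK_SOX10      Schwann   120    60  S100B,PanCK,SOX10,Vimentin
Schwann_CD44             Schwann   100    50  S100B,CD44,Vimentin
TAM_classical            Myeloid   350   120  CD45,Iba1,HLADR,CD74
TAM_alternative          Myeloid   120    60  CD45,Iba1,CD68,HLADR,CD163
TAM_CD68                 Myeloid   150    70  CD45,Iba1,CD68
Monocyte_transitioning   Myeloid   120    50  CD45,CD14,CD11b,Iba1
Neutrophil               Myeloid    60    25  CD45,CD11b
Neutrophil_perivascular  Myeloid    60    10  CD45,CD11b,CD74
CD8_TEMRA                Lymphoid  120    50  CD45,CD3,CD8a,CD45RA
CD8_TEMRA_AGTR1          Lymphoid   60    25  CD45,CD3,CD8a,CD45RA,AGTR1
CD4_TEMRA                Lymphoid   80    35  CD45,CD3,CD4,CD45RA
T_DN                     Lymphoid   40    15  CD45,CD3
Endothelium              Vascular   80    30  CD31,Vimentin
Pericyte                 Vascular   60    20  SMA,Vimentin
Erythrocyte              Other      40    20  CD235
Proliferating            Other      30    15  Ki67
Other_unresolved         Other      40    30  Vimentin
")
}

vs_profile <- function(high, base = 0.2, level = 5) {
  prof <- stats::setNames(rep(base, length(VS_MARKERS)), VS_MARKERS)
  hi <- intersect(strsplit(high, ",")[[1]], VS_MARKERS)
  prof[hi] <- level
  prof
}

#' Tissue specification emulating an Antoni A- or Antoni B-like ROI
#'
#' Antoni A ROIs are dense (~2700 cells/mm^2) and organised: Schwann cell
#' populations form Thomas clusters, vascular populations and hypoxic
#' perivascular neutrophils sit in perivascular halos around two vessels, and
#' classically activated-like TAMs co-cluster with CD8 TEMRA cells (shared
#' Thomas parents), which spatially excludes the Schwann clusters. Antoni B
#' ROIs are sparse (~1100 cells/mm^2) and loosely organised: most populations
#' are interspersed (CSR) with a single vessel, and CD8 TEMRA cells co-cluster
#' with PD-L1+ Schwann cells.
#'
#' @param region_class "AntoniA", "AntoniB" or "Mixed" (Mixed uses Antoni A
#'   organisation at intermediate density).
#' @param seed integer root seed.
#' @param scale multiplies all densities (use < 1 for fast tests).
#' @param batch_effects optional per-case batch multipliers.
#' @return a \code{\link{tissue_spec}}.
#' @export
vs_tissue_spec <- function(region_class = c("AntoniA", "AntoniB", "Mixed"),
                           seed = 1L, scale = 1, batch_effects = NULL) {
  region_class <- match.arg(region_class)
  tab <- vs_population_table()
  dens <- if (region_class == "AntoniB") tab$dens_b else
    if (region_class == "Mixed") (tab$dens_a + tab$dens_b) / 2 else tab$dens_a
  dens <- dens * scale
  a_like <- region_class != "AntoniB"
  pops <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$name[i]
    placement <- "CSR"; pp <- list()
    if (a_like && tab$group[i] == "Schwann") {
      placement <- "ThomasCluster"
      pp <- list(mean_offspring = 25, sigma_um = 30)
    }
    if (nm %in% c("Endothelium", "Pericyte", "Neutrophil_perivascular")) {
      placement <- "Perivascular"
    }
    population_spec(nm, tab$group[i], dens[i],
                    vs_profile(tab$high[i]), dispersion = 0.3,
                    placement = placement, placement_params = pp)
  })
  vessels <- if (a_like) list(
    vessel_spec(cbind(c(150, 400, 700, 900), c(100, 350, 450, 800)), 30),
    vessel_spec(cbind(c(100, 300, 600), c(850, 600, 900)), 30)
  ) else list(
    vessel_spec(cbind(c(200, 500, 850), c(200, 500, 850)), 30)
  )
  planted <- if (a_like) list(
    list(a = "TAM_classical", b = "CD8_TEMRA", strength = 0.7,
         sigma_um = 20, kappa_per_mm2 = 8)
  ) else list(
    list(a = "CD8_TEMRA", b = "Schwann_PDL1", strength = 0.6,
         sigma_um = 20, kappa_per_mm2 = 8)
  )
  tissue_spec(region_class = region_class, populations = pops,
              vessels = vessels, planted_pairs = planted,
              batch_effects = batch_effects, seed = seed)
}

#' Simulate a multi-case, multi-ROI study dataset
#'
#' Cases carry per-case log-normal batch effects, a disease-severity label, a
#' treatment label and a synthetic growth rate; each case contributes Antoni
#' A- and (for a subset) Antoni B-like ROIs.
#'
#' @param n_cases number of cases (default 13).
#' @param rois_a,rois_b ROIs of each class per case (Antoni B ROIs only for
#'   the first \code{n_cases_b} cases, emulating the rarity of B regions).
#' @param n_cases_b cases that contribute Antoni B ROIs (default
#'   \code{ceiling(n_cases / 2)}).
#' @param scale density scale passed to \code{\link{vs_tissue_spec}}.
#' @param seed integer root seed.
#' @return list with \code{cells} (row-bound cell table across all ROIs) and
#'   \code{cases} (case_id, severity, treatment, growth_rate).
#' @export
simulate_dataset <- function(n_cases = 13, rois_a = 2, rois_b = 1,
                             n_cases_b = ceiling(n_cases / 2),
                             scale = 1, seed = 1L) {
  case_ids <- sprintf("case%02d", seq_len(n_cases))
  be <- make_batch_effects(case_ids, VS_MARKERS, sdlog = 0.25, seed = seed)
  cases <- with_seed(substream_seed(seed, "cases"), {
    data.frame(case_id = case_ids,
               severity = sample(c("Mild", "Moderate", "Severe"), n_cases, TRUE),
               treatment = "naive",
               growth_rate = stats::rlnorm(n_cases, log(1.5), 0.5),
               stringsAsFactors = FALSE)
  })
  out <- list()
  for (ci in seq_len(n_cases)) {
    for (r in seq_len(rois_a)) {
      sp <- vs_tissue_spec("AntoniA", scale = scale, batch_effects = be,
                           seed = substream_seed(seed, sprintf("roiA:%d:%d", ci, r)))
      out[[length(out) + 1]] <-
        generate_roi(sp, roi_id = sprintf("%s_A%d", case_ids[ci], r),
                     case_id = case_ids[ci])
    }
    if (ci <= n_cases_b) for (r in seq_len(rois_b)) {
      sp <- vs_tissue_spec("AntoniB", scale = scale, batch_effects = be,
                           seed = substream_seed(seed, sprintf("roiB:%d:%d", ci, r)))
      out[[length(out) + 1]] <-
        generate_roi(sp, roi_id = sprintf("%s_B%d", case_ids[ci], r),
                     case_id = case_ids[ci])
    }
  }
  list(cells = do.call(rbind, out), cases = cases)
}

#' Canonical-marker rules for the four parent groups
#'
#' @return named list usable as \code{group_rules} in
#'   \code{\link{recluster_hierarchical}}.
#' @export
vs_group_rules <- function() {
  list(Schwann = c("S100B", "SOX10"),
       Myeloid = c("Iba1", "CD68", "CD163", "CD14", "CD11b"),
       Lymphoid = c("CD3", "CD4", "CD8a"),
       Vascular = c("SMA", "CD31"))
}

#' A small receptor-ligand pair table with planted effects
#'
#' Chemokine-axis-style pairs between TAMs and CD8 TEMRA cells plus inert
#' background pairs; folds are synthetic.
#'
#' @param fold fold-change planted on the signalling pairs (default 8).
#' @return data.frame with pair_id, ligand, receptor, sender, receiver, fold.
#' @export
vs_lr_pairs <- function(fold = 8) {
  data.frame(
    pair_id = c("CCL5_CCR5", "CXCL12_CXCR4", "BGPAIR1", "BGPAIR2", "BGPAIR3"),
    ligand = c("CCL5", "CXCL12", "LIGX1", "LIGX2", "LIGX3"),
    receptor = c("CCR5", "CXCR4", "RECX1", "RECX2", "RECX3"),
    sender = c("TAM_classical", "TAM_classical", "TAM_classical",
               "CD4_TEMRA", "Schwann_PDL1"),
    receiver = c("CD8_TEMRA", "CD8_TEMRA", "CD8_TEMRA", "CD8_TEMRA",
                 "CD8_TEMRA"),
    fold = c(fold, fold, 1, 1, 1),
    stringsAsFactors = FALSE)
}
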