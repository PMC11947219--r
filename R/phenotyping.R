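# Phenotyping: percentile normalisation, batch-balanced kNN graph,
# community-detection clustering, two-level (cluster -> group -> recluster)
# population assignment, and abundance tables.

#' Normalise marker intensities to a high percentile
#'
#' Each marker is divided by its q-th percentile across all cells (linear
#' interpolation between order statistics) and clipped to [0, 1]. Divisors are
#' stored in the \code{"divisors"} attribute so the same scaling can be reused;
#' passing stored divisors makes the operation idempotent. An all-zero marker
#' has no defined divisor: it is set to 0 and recorded in the
#' \code{"flagged_markers"} attribute.
#'
#' @param cells a cell table with raw marker columns.
#' @param q percentile in (50, 100] (default 99.9).
#' @param markers marker columns to normalise (default all).
#' @param divisors optional named vector of stored divisors to reuse.
#' @param keep_raw if TRUE, raw values are kept as \code{raw_<marker>} columns.
#' @return the cell table with marker columns normalised to [0, 1] and
#'   attributes \code{divisors} and \code{flagged_markers}.
#' @export
normalize_percentile <- function(cells, q = 99.9, markers = NULL,
                                 divisors = NULL, keep_raw = FALSE) {
  if (is.null(markers)) markers <- marker_cols(cells)
  if (q <= 50 || q > 100) stop("'q' must be in (50, 100]", call. = FALSE)
  if (isTRUE(attr(cells, "normalized"))) {
    message("table is already normalized: returning unchanged")
    return(cells)
  }
  flagged <- character()
  div <- stats::setNames(numeric(length(markers)), markers)
  for (m in markers) {
    v <- cells[[m]]
    if (keep_raw) cells[[paste0("raw_", m)]] <- v
    d <- if (!is.null(divisors)) divisors[[m]] else
      stats::quantile(v, q / 100, type = 7, names = FALSE)
    if (is.na(d) || d <= 0) {
      cells[[m]] <- rep(0, length(v))
      flagged <- c(flagged, m)
      div[m] <- NA_real_
    } else {
      cells[[m]] <- pmin(v / d, 1)
      div[m] <- d
    }
  }
  attr(cells, "divisors") <- div
  attr(cells, "flagged_markers") <- flagged
  attr(cells, "normalized") <- TRUE
  cells
}

#' Build a batch-balanced k-nearest-neighbour graph
#'
#' For every cell, its \code{k_per_batch} nearest neighbours (Euclidean
#' distance in normalised marker space) are found separately within each
#' batch, and the union of these directed neighbourhoods forms an undirected
#' weighted graph. Balancing neighbours across batches counteracts per-batch
#' intensity shifts at the graph level. Edge weight = 1 / (1 + distance).
#'
#' @param cells cell table (or numeric matrix of features).
#' @param batch_key column holding the batch (default \code{"case_id"});
#'   ignored when \code{cells} is a matrix and \code{batch} is given.
#' @param k_per_batch neighbours per batch (default 3). A batch with fewer
#'   cells contributes all of them (logged as a message).
#' @param markers marker columns to use (default all).
#' @param batch explicit batch vector overriding \code{batch_key}.
#' @return an undirected weighted \code{igraph} graph with one vertex per cell.
#' @export
build_bbknn_graph <- function(cells, batch_key = "case_id", k_per_batch = 3L,
                              markers = NULL, batch = NULL) {
  if (is.matrix(cells)) {
    X <- cells
    if (is.null(batch)) batch <- rep("b1", nrow(X))
  } else {
    if (is.null(markers)) markers <- marker_cols(cells)
    X <- as.matrix(cells[, markers, drop = FALSE])
    if (is.null(batch)) batch <- as.character(cells[[batch_key]])
  }
  n <- nrow(X)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (k_per_batch < 1) stop("k_per_batch must be >= 1", call. = FALSE)
  from <- integer(); to <- integer(); d <- numeric()
  for (b in unique(batch)) {
    ib <- which(batch == b)
    k_eff <- min(k_per_batch, length(ib))
    if (k_eff < k_per_batch)
      message(sprintf("batch '%s' has %d (< %d) cells: using all", b, length(ib), k_per_batch))
    # +1 then drop self-hits for in-batch queries
    nn <- RANN::nn2(X[ib, , drop = FALSE], X, k = min(k_eff + 1L, length(ib)))
    for (j in seq_len(ncol(nn$nn.idx))) {
      tgt <- ib[nn$nn.idx[, j]]
      keep <- tgt != seq_len(n)
      from <- c(from, which(keep)); to <- c(to, tgt[keep])
      d <- c(d, nn$nn.dists[keep, j])
    }
  }
  # keep at most k_per_batch non-self neighbours per (cell, batch), nearest first
  o <- order(from, d)
  from <- from[o]; to <- to[o]; d <- d[o]
  batch_of <- batch[to]
  key <- paste(from, batch_of)
  rk <- stats::ave(seq_along(key), key, FUN = seq_along)
  keep <- rk <= k_per_batch
  from <- from[keep]; to <- to[keep]; d <- d[keep]
  el <- cbind(pmin(from, to), pmax(from, to))
  dup <- duplicated(el)
  g <- igraph::graph_from_edgelist(el[!dup, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- 1 / (1 + d[!dup])
  g
}

#' Cluster a neighbour graph into cell populations
#'
#' Community detection by Leiden modularity optimisation at the given
#' resolution; deterministic for a fixed seed.
#'
#' @param graph an igraph graph (weighted edges used if present).
#' @param resolution resolution parameter (default 1).
#' @param seed integer seed.
#' @param n_iterations Leiden iterations (default 10).
#' @return integer cluster labels, one per vertex.
#' @export
cluster_cells <- function(graph, resolution = 1, seed = 1L, n_iterations = 10L) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  with_seed(substream_seed(seed, "leiden"), {
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
    as.integer(igraph::membership(cl))
  })
}

#' Two-level phenotyping: assign parent groups, then recluster within groups
#'
#' Coarse clusters are mapped to parent groups by canonical-marker means: a
#' cluster is assigned to the group whose canonical markers have the highest
#' mean normalised expression in that cluster, or to "Other" when no group
#' score reaches \code{min_score}. Cells of each parent group are then
#' re-embedded and re-clustered at the fine resolution, and fine clusters are
#' annotated into named populations by marker rules (see
#' \code{\link{annotate_populations}}).
#'
#' @param cells normalised cell table.
#' @param coarse integer coarse cluster labels (e.g. from
#'   \code{\link{cluster_cells}}).
#' @param group_rules named list: parent group -> character vector of canonical
#'   markers.
#' @param population_rules named list: population -> list(group =, pos =,
#'   neg = ) used for annotation; NULL keeps "<group>.<k>" labels.
#' @param fine_resolution resolution for the within-group reclustering.
#' @param k_per_batch,batch_key passed to \code{\link{build_bbknn_graph}}.
#' @param min_score minimum canonical-marker mean for a group assignment
#'   (default 0.1).
#' @param seed integer seed.
#' @return list with \code{population} (per cell), \code{parent_group}
#'   (per cell) and \code{fine_cluster} (per cell, "<group>.<k>").
#' @export
recluster_hierarchical <- function(cells, coarse, group_rules,
                                   population_rules = NULL,
                                   fine_resolution = 1.5, k_per_batch = 3L,
                                   batch_key = "case_id", min_score = 0.1,
                                   seed = 1L) {
  markers <- marker_cols(cells)
  groups <- names(group_rules)
  # score each coarse cluster against each group's canonical markers
  cl_levels <- sort(unique(coarse))
  score <- sapply(groups, function(g) {
    ms <- intersect(group_rules[[g]], markers)
    if (length(ms) == 0) return(rep(0, length(cl_levels)))
    vapply(cl_levels, function(cl)
      mean(colMeans(cells[coarse == cl, ms, drop = FALSE])), 0)
  })
  score <- matrix(score, nrow = length(cl_levels),
                  dimnames = list(cl_levels, groups))
  grp_of_cluster <- apply(score, 1, function(s)
    if (max(s) >= min_score) groups[which.max(s)] else "Other")
  parent_group <- unname(grp_of_cluster[as.character(coarse)])

  fine <- character(length(coarse))
  for (g in unique(parent_group)) {
    ig <- which(parent_group == g)
    if (length(ig) <= max(2L, k_per_batch)) {
      message(sprintf("group '%s' has %d cells: kept as one population", g, length(ig)))
      fine[ig] <- paste0(g, ".1")
      next
    }
    gg <- build_bbknn_graph(cells[ig, , drop = FALSE], batch_key = batch_key,
                            k_per_batch = k_per_batch, markers = markers)
    sub <- cluster_cells(gg, resolution = fine_resolution,
                         seed = substream_seed(seed, paste0("fine:", g)))
    fine[ig] <- paste0(g, ".", sub)
  }
  population <- if (is.null(population_rules)) fine else
    annotate_populations(cells, fine, parent_group, population_rules)
  list(population = population, parent_group = parent_group,
       fine_cluster = fine)
}

#' Annotate fine clusters into named populations by marker rules
#'
#' A rule is \code{list(group =, pos = c(markers...), neg = c(markers...))}.
#' For each fine cluster (restricted to rules of its parent group) the rule
#' with the largest margin \code{min(pos means) - max(neg means)} wins,
#' provided all positive markers exceed \code{pos_threshold} and all negative
#' markers fall below it; clusters matching no rule become "Other".
#'
#' @param cells normalised cell table.
#' @param fine fine cluster labels per cell.
#' @param parent_group parent group per cell.
#' @param rules named list of rules (names are population labels).
#' @param pos_threshold expression threshold on cluster means (default 0.3).
#' @return character population label per cell.
#' @export
annotate_populations <- function(cells, fine, parent_group, rules,
                                 pos_threshold = 0.3) {
  out <- rep("Other", length(fine))
  for (fc in unique(fine)) {
    sel <- fine == fc
    grp <- parent_group[which(sel)[1]]
    mu <- colMeans(cells[sel, marker_cols(cells), drop = FALSE])
    best <- NULL; best_margin <- -Inf
    for (nm in names(rules)) {
      r <- rules[[nm]]
      if (!is.null(r$group) && r$group != grp) next
      pos <- mu[intersect(r$pos, names(mu))]
      neg <- mu[intersect(r$neg %||% character(), names(mu))]
      if (length(pos) == 0 || any(pos < pos_threshold)) next
      if (length(neg) > 0 && any(neg >= pos_threshold)) next
      margin <- min(pos) - if (length(neg)) max(neg) else 0
      if (margin > best_margin) { best <- nm; best_margin <- margin }
    }
    if (!is.null(best)) out[sel] <- best
  }
  out
}

#' Relative abundance of populations per ROI or per case
#'
#' ROI-level rows are per-(case, ROI) population proportions (each row sums to
#' 1); case level averages a case's ROI rows, mirroring case-averaged
#' abundance analysis. ROIs in \code{exclude_regions} (transition zones by
#' default) are omitted before tabulation.
#'
#' @param cells cell table with population labels.
#' @param level "roi" or "case".
#' @param exclude_regions region classes to drop (default "Mixed").
#' @param label_col column holding the label to tabulate (default
#'   "population"; use "cn" for neighbourhood abundances).
#' @return data.frame with case_id (and roi_id, region at ROI level) plus one
#'   proportion column per population.
#' @export
abundance_table <- function(cells, level = c("roi", "case"),
                            exclude_regions = "Mixed",
                            label_col = "population") {
  level <- match.arg(level)
  keep <- !(cells$region %in% exclude_regions)
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0)
    stop("no cells left after region exclusion", call. = FALSE)
  pops <- sort(unique(as.character(cells[[label_col]])))
  tab <- table(paste(cells$case_id, cells$roi_id, sep = "\r"),
               factor(as.character(cells[[label_col]]), levels = pops))
  prop <- prop.table(tab, 1)
  key <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  region <- cells$region[match(rownames(tab),
                               paste(cells$case_id, cells$roi_id, sep = "\r"))]
  roi_df <- data.frame(case_id = key[, 1], roi_id = key[, 2], region = region,
                       stringsAsFactors = FALSE)
  roi_df <- cbind(roi_df, as.data.frame.matrix(prop))
  rownames(roi_df) <- NULL
  if (level == "roi") return(roi_df)
  agg <- stats::aggregate(roi_df[, pops, drop = FALSE],
                          by = list(case_id = roi_df$case_id), FUN = mean)
  agg
}
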