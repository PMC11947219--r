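# Cross-pair correlation functions (cross-PCF) with the gr20 summary and
# label-permutation significance, plus adjacency cell-network (ACN) contact
# statistics. ROIs are analysed independently; all distances are in um within
# a rectangular observation window.

# -- exact circle/rectangle geometry -----------------------------------------

# Area of {0 <= x <= w, 0 <= y <= h, x^2 + y^2 <= r^2} for w, h >= 0.
quadrant_area <- function(w, h, r) {
  w <- pmin(w, r); h <- pmin(h, r)
  out <- numeric(length(w))
  full <- w * w + h * h <= r * r
  out[full] <- (w * h)[full]
  part <- !full
  if (any(part)) {
    wp <- w[part]; hp <- h[part]; rp <- if (length(r) > 1) r[part] else r
    # x-range where the arc is below h: x in [x0, x1]
    x0 <- sqrt(pmax(rp^2 - hp^2, 0))
    x1 <- pmin(wp, rp)
    seg <- function(x, r) (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(pmax(x / r, -1), 1))) / 2
    out[part] <- hp * x0 + (seg(x1, rp) - seg(x0, rp))
  }
  out
}

# Area of the disc of radius r centred at (cx, cy) intersected with the
# rectangle [0, W] x [0, H]; exact, vectorised over centres.
circle_rect_area <- function(cx, cy, r, W, H) {
  if (r <= 0) return(numeric(length(cx)))
  qa <- function(w, h) {
    s <- sign(w) * sign(h)
    s * quadrant_area(abs(w), abs(h), r)
  }
  qa(W - cx, H - cy) - qa(-cx, H - cy) - qa(W - cx, -cy) + qa(-cx, -cy)
}

# -- cross-PCF ----------------------------------------------------------------

#' Cross-pair correlation function between two cell populations
#'
#' Estimates g_AB(r) on distance bins [r_k, r_k + dr): for each A cell i, the
#' count of B cells in the annulus is divided by the B intensity times the
#' annulus area clipped to the window (exact geometric edge correction), and
#' the result is averaged over A cells. Values above 1 indicate spatial
#' attraction at that range, below 1 depletion. gr20 is the value of the final
#' bin ([r_max - dr, r_max), i.e. [19, 20) um at the defaults).
#'
#' @param cells cell table of a single ROI (columns x_um, y_um, population).
#' @param type_a,type_b population labels ('A' and 'B'; may be equal, in which
#'   case a cell is never its own neighbour).
#' @param r_max maximum distance in um (default 20).
#' @param dr bin width in um (default 1).
#' @param window c(width, height) of the ROI in um; defaults to the span of
#'   the data rounded up, but should be given explicitly.
#' @param edge_correction use the exact annulus-in-rectangle area (default
#'   TRUE); FALSE uses the full annulus area.
#' @return an object of class \code{pcf_result}: list with pair, breaks, r
#'   (bin left edges), g, gr20, n_a, n_b, empty flag.
#' @export
cross_pcf <- function(cells, type_a, type_b, r_max = 20, dr = 1,
                      window = NULL, edge_correction = TRUE) {
  if (is.null(window)) window <- c(ceiling(max(cells$x_um, 1)), ceiling(max(cells$y_um, 1)))
  W <- window[1]; H <- window[2]
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1L
  ia <- which(cells$population == type_a)
  ib <- which(cells$population == type_b)
  if (length(ia) == 0 || length(ib) == 0) {
    return(structure(list(pair = c(type_a, type_b), breaks = breaks,
                          r = breaks[-length(breaks)], g = rep(NA_real_, nb),
                          gr20 = NA_real_, n_a = length(ia), n_b = length(ib),
                          empty = TRUE), class = "pcf_result"))
  }
  ax <- cells$x_um[ia]; ay <- cells$y_um[ia]
  bx <- cells$x_um[ib]; by <- cells$y_um[ib]
  rho_b <- length(ib) / (W * H)
  # pair counts per (A cell, bin)
  cnt <- matrix(0, length(ia), nb)
  for (k in seq_along(ia)) {
    d <- sqrt((bx - ax[k])^2 + (by - ay[k])^2)
    if (type_a == type_b) d <- d[ib != ia[k]]
    d <- d[d < r_max]
    if (length(d)) {
      bin <- pmin(floor(d / dr) + 1L, nb)
      cnt[k, ] <- tabulate(bin, nbins = nb)
    }
  }
  # annulus areas per (A cell, bin)
  disc <- sapply(breaks, function(r)
    if (edge_correction) circle_rect_area(ax, ay, r, W, H) else
      rep(pi * r^2, length(ax)))
  disc <- matrix(disc, nrow = length(ax))
  ann <- disc[, -1, drop = FALSE] - disc[, -ncol(disc), drop = FALSE]
  g <- colMeans(cnt / (rho_b * ann))
  structure(list(pair = c(type_a, type_b), breaks = breaks,
                 r = breaks[-length(breaks)], g = g, gr20 = g[nb],
                 n_a = length(ia), n_b = length(ib), empty = FALSE),
            class = "pcf_result")
}

#' @export
print.pcf_result <- function(x, ...) {
  cat(sprintf("cross-PCF %s -> %s (n_A = %d, n_B = %d)\n",
              x$pair[1], x$pair[2], x$n_a, x$n_b))
  if (x$empty) cat("  empty: one population absent\n") else
    cat(sprintf("  gr%g = %.3f over %d bins\n", max(x$breaks), x$gr20,
                length(x$g)))
  invisible(x)
}

# Precompute, for one ROI, everything needed to evaluate gr20 under arbitrary
# relabellings: the ordered point pairs whose distance falls in the final bin
# and the per-point final-bin annulus areas. gr20 for labels L is then
#   |W| / (n_A n_B) * sum over stored pairs (i, j) with L[i]=A, L[j]=B of 1/a_i.
pcf_pair_structure <- function(x, y, window, r_max = 20, dr = 1,
                               edge_correction = TRUE) {
  W <- window[1]; H <- window[2]
  n <- length(x)
  lo <- r_max - dr
  a_hi <- if (edge_correction) circle_rect_area(x, y, r_max, W, H) else
    rep(pi * r_max^2, n)
  a_lo <- if (edge_correction) circle_rect_area(x, y, lo, W, H) else
    rep(pi * lo^2, n)
  a <- a_hi - a_lo
  pi_ <- integer(); pj <- integer()
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    j <- which(d2 >= lo^2 & d2 < r_max^2)
    j <- j[j != i]
    if (length(j)) { pi_ <- c(pi_, rep.int(i, length(j))); pj <- c(pj, j) }
  }
  list(i = pi_, j = pj, w = 1 / a[pi_], area = W * H, n = n)
}

gr_from_structure <- function(st, labels, type_a, type_b) {
  n_a <- sum(labels == type_a); n_b <- sum(labels == type_b)
  if (n_a == 0 || n_b == 0) return(NA_real_)
  sel <- labels[st$i] == type_a & labels[st$j] == type_b
  st$area / (n_a * n_b) * sum(st$w[sel])
}

#' Permutation significance of the gr20 summary
#'
#' Population labels are permuted among all cells of the ROI (positions and
#' the label multiset fixed) and gr20 recomputed for each permutation. The
#' two-sided p-value is (1 + #{|perm - 1| >= |obs - 1|}) / (n_perm + 1);
#' direction is "enriched" when observed gr20 > 1 and significant, "depleted"
#' when < 1 and significant, otherwise "ns".
#'
#' @param cells cell table of a single ROI.
#' @param type_a,type_b the ordered pair.
#' @param n_perm number of permutations (default 1000; < 99 draws a warning).
#' @param seed integer seed (permutations are bit-reproducible).
#' @param r_max,dr,window,edge_correction as in \code{\link{cross_pcf}}.
#' @param alpha significance level used for the direction call (default 0.05).
#' @return list with gr20 (observed), p_value, direction, perm (the permuted
#'   gr20 values) and the observed \code{pcf_result}.
#' @export
pcf_significance <- function(cells, type_a, type_b, n_perm = 1000, seed = 1L,
                             r_max = 20, dr = 1, window = NULL,
                             edge_correction = TRUE, alpha = 0.05) {
  if (n_perm < 99) warning("n_perm < 99 gives poor p-value resolution")
  if (is.null(window)) window <- c(ceiling(max(cells$x_um, 1)), ceiling(max(cells$y_um, 1)))
  obs <- cross_pcf(cells, type_a, type_b, r_max = r_max, dr = dr,
                   window = window, edge_correction = edge_correction)
  if (obs$empty)
    return(list(gr20 = NA_real_, p_value = NA_real_, direction = "ns",
                perm = numeric(), observed = obs))
  st <- pcf_pair_structure(cells$x_um, cells$y_um, window, r_max, dr,
                           edge_correction)
  labels <- as.character(cells$population)
  perm <- with_seed(substream_seed(seed, "pcfperm"), {
    vapply(seq_len(n_perm), function(p)
      gr_from_structure(st, sample(labels), type_a, type_b), 0)
  })
  perm[is.na(perm)] <- 1  # degenerate permutation: no information, null-centred
  p <- (1 + sum(abs(perm - 1) >= abs(obs$gr20 - 1))) / (n_perm + 1)
  direction <- if (p < alpha) {
    if (obs$gr20 > 1) "enriched" else "depleted"
  } else "ns"
  list(gr20 = obs$gr20, p_value = p, direction = direction, perm = perm,
       observed = obs)
}

#' Aggregate significant gr20 values into a pair matrix
#'
#' Per ordered pair, p-values are BH-adjusted across pairs within each ROI; a
#' pair is called significant for the region class when its q-value is below
#' \code{alpha} in at least \code{consensus_frac} of the ROIs where both
#' populations are present. The matrix entry is the mean gr20 over ROIs for
#' significant pairs and NA (masked) otherwise.
#'
#' @param results data.frame with columns type_a, type_b, roi_id, gr20,
#'   p_value (one row per pair per ROI, e.g. rows built from
#'   \code{\link{pcf_significance}}).
#' @param alpha significance level after adjustment (default 0.05).
#' @param consensus_frac fraction of ROIs required (default 0.5, i.e.
#'   majority).
#' @return list with \code{matrix} (mean gr20, types x types), \code{mask}
#'   (logical, TRUE = significant) and \code{long} (per-pair summary).
#' @export
pcf_heatmap <- function(results, alpha = 0.05, consensus_frac = 0.5) {
  results <- results[!is.na(results$gr20), , drop = FALSE]
  results$q_value <- stats::ave(results$p_value, results$roi_id,
                                FUN = function(p) stats::p.adjust(p, "BH"))
  key <- paste(results$type_a, results$type_b, sep = "\r")
  agg <- lapply(split(results, key), function(df)
    data.frame(type_a = df$type_a[1], type_b = df$type_b[1],
               n_roi = nrow(df), mean_gr20 = mean(df$gr20),
               frac_sig = mean(df$q_value < alpha)))
  long <- do.call(rbind, agg)
  long$significant <- long$frac_sig >= consensus_frac & long$n_roi > 0
  rownames(long) <- NULL
  types <- sort(unique(c(long$type_a, long$type_b)))
  mat <- matrix(NA_real_, length(types), length(types),
                dimnames = list(types, types))
  msk <- matrix(FALSE, length(types), length(types),
                dimnames = list(types, types))
  for (i in seq_len(nrow(long))) {
    mat[long$type_a[i], long$type_b[i]] <- long$mean_gr20[i]
    msk[long$type_a[i], long$type_b[i]] <- long$significant[i]
  }
  mat[!msk] <- NA_real_
  list(matrix = mat, mask = msk, long = long)
}

# -- adjacency cell network ---------------------------------------------------

#' Adjacency cell-network contact statistics for one ordered pair
#'
#' Two cells are "in contact" when their centroid distance is at most
#' \code{contact_radius} (a cell is never its own contact). Returns the number
#' of A cells in contact with at least one B cell and the proportion of B
#' cells contacted by at least one A cell.
#'
#' @param cells cell table of one ROI.
#' @param type_a,type_b ordered pair of population labels.
#' @param contact_radius contact distance in um (default 10, about one cell
#'   diameter).
#' @return data.frame row: type_a, type_b, n_a, n_b, n_a_touching_b,
#'   prop_b_touched_by_a, flagged (TRUE when n_b = 0).
#' @export
acn <- function(cells, type_a, type_b, contact_radius = 10) {
  stopifnot(contact_radius > 0)
  ia <- which(cells$population == type_a)
  ib <- which(cells$population == type_b)
  if (length(ib) == 0 || length(ia) == 0) {
    return(data.frame(type_a = type_a, type_b = type_b,
                      n_a = length(ia), n_b = length(ib),
                      n_a_touching_b = 0L, prop_b_touched_by_a = 0,
                      flagged = TRUE))
  }
  ax <- cells$x_um[ia]; ay <- cells$y_um[ia]
  bx <- cells$x_um[ib]; by <- cells$y_um[ib]
  r2 <- contact_radius^2
  a_touch <- logical(length(ia)); b_touch <- logical(length(ib))
  for (k in seq_along(ia)) {
    d2 <- (bx - ax[k])^2 + (by - ay[k])^2
    hit <- d2 <= r2
    if (type_a == type_b) hit[ib == ia[k]] <- FALSE
    if (any(hit)) { a_touch[k] <- TRUE; b_touch[hit] <- TRUE }
  }
  data.frame(type_a = type_a, type_b = type_b,
             n_a = length(ia), n_b = length(ib),
             n_a_touching_b = sum(a_touch),
             prop_b_touched_by_a = mean(b_touch), flagged = FALSE)
}

# Contact pair list of one ROI for fast permutation: ordered pairs (i, j),
# i != j, with centroid distance <= radius.
acn_pair_structure <- function(x, y, radius) {
  n <- length(x); r2 <- radius^2
  pi_ <- integer(); pj <- integer()
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    j <- which(d2 <= r2); j <- j[j != i]
    if (length(j)) { pi_ <- c(pi_, rep.int(i, length(j))); pj <- c(pj, j) }
  }
  list(i = pi_, j = pj, n = n)
}

prop_from_structure <- function(st, labels, type_a, type_b) {
  n_b <- sum(labels == type_b)
  if (n_b == 0) return(NA_real_)
  sel <- labels[st$i] == type_a & labels[st$j] == type_b
  length(unique(st$j[sel])) / n_b
}

#' Permutation significance for ACN contact statistics across pairs of one ROI
#'
#' For every ordered pair, the proportion of B cells touched by A is compared
#' with its distribution under label permutations (positions fixed, label
#' multiset fixed); the two-sided p-value is
#' (1 + #{|perm - E| >= |obs - E|}) / (n_perm + 1) with E the permutation mean.
#' p-values are BH-adjusted across pairs within the ROI.
#'
#' @param cells cell table of one ROI.
#' @param pairs data.frame with columns type_a, type_b (default: all ordered
#'   pairs of populations present).
#' @param contact_radius contact distance in um (default 10).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame: one row per pair with the \code{\link{acn}} statistics
#'   plus p_value and q_value.
#' @export
acn_significance <- function(cells, pairs = NULL, contact_radius = 10,
                             n_perm = 1000, seed = 1L) {
  pops <- sort(unique(as.character(cells$population)))
  if (is.null(pairs)) pairs <- expand.grid(type_a = pops, type_b = pops,
                                           stringsAsFactors = FALSE)
  st <- acn_pair_structure(cells$x_um, cells$y_um, contact_radius)
  labels <- as.character(cells$population)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$type_a[k]; b <- pairs$type_b[k]
    base <- acn(cells, a, b, contact_radius)
    if (base$flagged) { base$p_value <- NA_real_; return(base) }
    perm <- with_seed(substream_seed(seed, paste0("acnperm:", a, ":", b)), {
      vapply(seq_len(n_perm), function(p)
        prop_from_structure(st, sample(labels), a, b), 0)
    })
    e <- mean(perm)
    base$p_value <- (1 + sum(abs(perm - e) >= abs(base$prop_b_touched_by_a - e))) /
      (n_perm + 1)
    base
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], "BH")
  out$roi_id <- if (!is.null(cells$roi_id) && nrow(cells)) cells$roi_id[1] else NA
  out
}

#' Consensus interaction network for a region class
#'
#' An edge (A, B) exists when the ACN pair is significant (q < alpha) in at
#' least \code{consensus_frac} of the class's ROIs where it was testable.
#' Edge weight is the mean gr20 of the pair over those ROIs (co-localisation
#' strength); node size is the mean abundance of each population.
#'
#' @param acn_results row-bound \code{\link{acn_significance}} output over the
#'   ROIs of one region class.
#' @param pcf_results data.frame with type_a, type_b, roi_id, gr20 (for edge
#'   weights); may be NULL (weights NA).
#' @param abundance ROI-level \code{\link{abundance_table}} for node sizes;
#'   may be NULL.
#' @param alpha q-value threshold (default 0.05).
#' @param consensus_frac fraction of testable ROIs required (default 0.5).
#' @return list with \code{edges} (type_a, type_b, frac_sig, weight),
#'   \code{nodes} (population, mean_abundance) and \code{graph} (igraph).
#' @export
acn_network <- function(acn_results, pcf_results = NULL, abundance = NULL,
                        alpha = 0.05, consensus_frac = 0.5) {
  ok <- !is.na(acn_results$q_value)
  res <- acn_results[ok, , drop = FALSE]
  key <- paste(res$type_a, res$type_b, sep = "\r")
  agg <- lapply(split(res, key), function(df)
    data.frame(type_a = df$type_a[1], type_b = df$type_b[1],
               n_roi = nrow(df), frac_sig = mean(df$q_value < alpha)))
  agg <- do.call(rbind, agg)
  edges <- agg[agg$frac_sig >= consensus_frac & agg$n_roi > 0, , drop = FALSE]
  edges$weight <- rep(NA_real_, nrow(edges))
  if (!is.null(pcf_results) && nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      sel <- pcf_results$type_a == edges$type_a[i] &
        pcf_results$type_b == edges$type_b[i]
      if (any(sel)) edges$weight[i] <- mean(pcf_results$gr20[sel], na.rm = TRUE)
    }
  }
  rownames(edges) <- NULL
  pops <- sort(unique(c(acn_results$type_a, acn_results$type_b)))
  nodes <- data.frame(population = pops, mean_abundance = NA_real_)
  if (!is.null(abundance)) {
    for (i in seq_along(pops))
      if (pops[i] %in% colnames(abundance))
        nodes$mean_abundance[i] <- mean(abundance[[pops[i]]])
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("type_a", "type_b", "weight", "frac_sig")],
    directed = TRUE, vertices = nodes)
  list(edges = edges, nodes = nodes, graph = g)
}
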