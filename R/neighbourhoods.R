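# Cellular neighbourhoods (CNs): hop-aggregated features on a trimmed
# Delaunay graph, Gaussian-mixture clustering with Fowlkes-Mallows stability
# selection of K, then CN enrichment, abundance and proximity analysis.

#' Build the spatial graph of one ROI
#'
#' Delaunay triangulation of the cell centroids with edges longer than
#' \code{max_edge_um} removed; undirected, no self-loops. Delaunay avoids the
#' density-dependent choice of k that a kNN graph would need, and the trim
#' stops spurious long edges across sparse regions.
#'
#' @param cells cell table of one ROI (x_um, y_um).
#' @param max_edge_um trim length in um (default 30).
#' @return an undirected igraph graph with one vertex per cell (in row order).
#' @export
build_spatial_graph <- function(cells, max_edge_um = 30) {
  n <- nrow(cells)
  if (n < 2) return(igraph::make_empty_graph(n, directed = FALSE))
  if (n == 2) {
    d <- sqrt(diff(cells$x_um)^2 + diff(cells$y_um)^2)
    g <- igraph::make_empty_graph(2, directed = FALSE)
    if (d <= max_edge_um) g <- igraph::add_edges(g, c(1, 2))
    return(g)
  }
  dxy <- deldir::deldir(cells$x_um, cells$y_um, suppressMsge = TRUE)
  el <- as.matrix(dxy$delsgs[, c("ind1", "ind2")])
  len <- sqrt((dxy$delsgs$x1 - dxy$delsgs$x2)^2 +
              (dxy$delsgs$y1 - dxy$delsgs$y2)^2)
  el <- el[len <= max_edge_um, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  igraph::simplify(g)
}

#' Aggregate marker features over hop shells of the spatial graph
#'
#' Each cell's feature vector is the concatenation of its own normalised
#' marker vector and, for each hop shell 1..L, the mean marker vector over
#' cells at exactly that graph distance. Empty shells contribute zeros and are
#' counted in the \code{"n_empty_shells"} attribute.
#'
#' @param cells cell table of one ROI with normalised markers.
#' @param graph spatial graph from \code{\link{build_spatial_graph}}.
#' @param L hop depth (default 3; 0 returns the markers unchanged).
#' @param markers marker columns (default all).
#' @return numeric matrix, n_cells x (L + 1) * n_markers.
#' @export
aggregate_features <- function(cells, graph, L = 3L, markers = NULL) {
  if (is.null(markers)) markers <- marker_cols(cells)
  X <- as.matrix(cells[, markers, drop = FALSE])
  n <- nrow(X)
  stopifnot(L >= 0, igraph::vcount(graph) == n)
  out <- X
  colnames(out) <- paste0(markers, ".hop0")
  if (L == 0) { attr(out, "n_empty_shells") <- 0L; return(out) }
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE) > 0
  reached <- Matrix::Diagonal(n, TRUE)  # hops < current
  frontier <- A
  n_empty <- 0L
  for (l in seq_len(L)) {
    shell <- frontier & !reached
    deg <- Matrix::rowSums(shell)
    Sm <- as.matrix(shell %*% X)
    Sm[deg > 0, ] <- Sm[deg > 0, , drop = FALSE] / deg[deg > 0]
    Sm[deg == 0, ] <- 0
    n_empty <- n_empty + sum(deg == 0)
    colnames(Sm) <- paste0(markers, ".hop", l)
    out <- cbind(out, Sm)
    reached <- reached | shell
    frontier <- (shell %*% A) > 0
  }
  attr(out, "n_empty_shells") <- n_empty
  out
}

#' Fowlkes-Mallows index between two labelings
#'
#' Pair-counting similarity TP / sqrt((TP + FP)(TP + FN)) over the
#' co-clustered item pairs, computed from the contingency table; invariant
#' under relabelling of either side and 1 iff the partitions coincide.
#'
#' @param a,b label vectors of equal length (>= 2 items).
#' @return FMI in [0, 1].
#' @export
fowlkes_mallows <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  tab <- table(a, b)
  tk <- sum(tab^2) - n          # 2 * TP
  pk <- sum(rowSums(tab)^2) - n # 2 * (TP + FP)
  qk <- sum(colSums(tab)^2) - n # 2 * (TP + FN)
  if (pk == 0 || qk == 0) return(if (pk == qk) 1 else 0)
  tk / sqrt(pk * qk)
}

# One GMM fit (full covariance) with randomised k-means initialisation; the
# conjugate prior acts as a covariance regulariser (variance floor).
gmm_fit <- function(X, K, seed) {
  with_seed(seed, {
    km <- stats::kmeans(X, centers = K, nstart = 1, iter.max = 30)
    z <- outer(km$cluster, seq_len(K), `==`) * 1
    fit <- tryCatch(
      mclust::meVVV(data = X, z = z, prior = mclust::priorControl()),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$loglik) || any(is.na(fit$z))) {
      # degenerate covariance even under the prior: diagonal fallback, logged
      message(sprintf("GMM K=%d: full covariance degenerate, using diagonal", K))
      fit <- mclust::meVVI(data = X, z = z, prior = mclust::priorControl())
    }
    list(labels = apply(fit$z, 1, which.max), loglik = fit$loglik)
  })
}

#' Select the number of neighbourhoods by Fowlkes-Mallows stability
#'
#' For each K in \code{k_range}, R Gaussian-mixture models (full covariance,
#' randomised initialisation) are fitted. Stability is the mean pairwise FMI
#' among the R labelings at K ("within" mode, default) or the mean FMI
#' between the fits at K and those at K - 1 and K + 1 ("between" mode). K* is
#' the K with maximal stability (ties to the smallest K); the returned model
#' is the best-likelihood fit at K*.
#'
#' @param features feature matrix (cells x features), e.g. from
#'   \code{\link{aggregate_features}}.
#' @param k_range integer vector of K values to try.
#' @param R repeats per K (default 10; must be >= 2).
#' @param seed integer root seed (fit r at K uses substream "gmm:<K>:<r>").
#' @param mode "within" or "between".
#' @return list of class \code{stability_curve}: k_range, stability, best_k,
#'   labels (per-cell CN label of the selected model), loglik, repeats,
#'   mode, all_labels (list of matrices of labelings per K).
#' @export
select_k <- function(features, k_range, R = 10L, seed = 1L,
                     mode = c("within", "between")) {
  mode <- match.arg(mode)
  if (R < 2) stop("stability needs R >= 2 repeats", call. = FALSE)
  n <- nrow(features)
  if (any(k_range < 2) || any(k_range > n / 10))
    stop("k_range must lie within [2, n/10]", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(K)
    lapply(seq_len(R), function(r)
      gmm_fit(features, K, substream_seed(seed, sprintf("gmm:%d:%d", K, r)))))
  names(fits) <- as.character(k_range)
  lab_of <- function(K) lapply(fits[[as.character(K)]], `[[`, "labels")
  stability <- vapply(seq_along(k_range), function(ki) {
    K <- k_range[ki]
    if (mode == "within") {
      ls <- lab_of(K)
      pairs <- utils::combn(R, 2)
      mean(apply(pairs, 2, function(p) fowlkes_mallows(ls[[p[1]]], ls[[p[2]]])))
    } else {
      neigh <- intersect(c(K - 1L, K + 1L), k_range)
      if (length(neigh) == 0) return(NA_real_)
      ls <- lab_of(K)
      mean(unlist(lapply(neigh, function(Kn) {
        lsn <- lab_of(Kn)
        vapply(seq_len(R), function(r) fowlkes_mallows(ls[[r]], lsn[[r]]), 0)
      })))
    }
  }, 0)
  best_k <- k_range[which.max(stability)]  # which.max takes the first (smallest K) on ties
  best_fits <- fits[[as.character(best_k)]]
  ll <- vapply(best_fits, `[[`, 0, "loglik")
  chosen <- best_fits[[which.max(ll)]]
  structure(list(k_range = k_range, stability = stability, best_k = best_k,
                 labels = chosen$labels, loglik = chosen$loglik, repeats = R,
                 mode = mode,
                 all_labels = lapply(k_range, function(K)
                   do.call(cbind, lab_of(K)))),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("FMI stability over K = {%s} (%d repeats, %s mode)\n",
              paste(x$k_range, collapse = ", "), x$repeats, x$mode))
  cat(sprintf("  selected K* = %d (stability %.3f)\n", x$best_k,
              x$stability[x$k_range == x$best_k]))
  invisible(x)
}

#' Cell-type enrichment of each cellular neighbourhood
#'
#' enrichment(cn, t) = fraction of type t among the cells of cn divided by the
#' overall fraction of type t; 1 means the type is represented at its global
#' rate, 0 means absent.
#'
#' @param cn CN label per cell.
#' @param population cell-type label per cell.
#' @return matrix CNs x types of enrichment ratios.
#' @export
cn_enrichment <- function(cn, population) {
  tab <- table(cn, population)
  prop <- prop.table(tab, 1)
  overall <- prop.table(table(population))
  sweep(prop, 2, as.numeric(overall[colnames(prop)]), `/`)
}

#' CN-CN proximity enrichment (sender rows, receiver columns)
#'
#' Edges of the spatial graphs are pooled across the ROIs of one region class.
#' observed(i, j) is the fraction of edge endpoints leaving CN-i cells that
#' land on CN-j cells; the null shuffles CN labels within each ROI on the
#' fixed graphs. The score is (observed - null mean) / null sd, so positive
#' values mean the two neighbourhoods abut more than label exchange predicts.
#'
#' @param cn_labels list of per-ROI CN label vectors.
#' @param graphs list of per-ROI spatial graphs (same order and lengths).
#' @param n_perm label shuffles (default 200).
#' @param seed integer seed.
#' @return list with \code{score} (z-score matrix), \code{observed},
#'   \code{null_mean}, \code{null_sd}.
#' @export
cn_proximity <- function(cn_labels, graphs, n_perm = 200, seed = 1L) {
  stopifnot(length(cn_labels) == length(graphs))
  cns <- sort(unique(unlist(cn_labels)))
  k <- length(cns)
  if (k == 1) {
    m <- matrix(0, 1, 1, dimnames = list(cns, cns))
    return(list(score = m, observed = m + 1, null_mean = m + 1, null_sd = m))
  }
  edge_idx <- lapply(graphs, function(g) igraph::as_edgelist(g, names = FALSE))
  directed_counts <- function(labels_list) {
    M <- matrix(0, k, k, dimnames = list(cns, cns))
    for (r in seq_along(labels_list)) {
      el <- edge_idx[[r]]
      if (nrow(el) == 0) next
      li <- match(labels_list[[r]][el[, 1]], cns)
      lj <- match(labels_list[[r]][el[, 2]], cns)
      # undirected edges contribute to both directions
      for (d in 1:2) {
        t <- if (d == 1) cbind(li, lj) else cbind(lj, li)
        M <- M + unclass(table(factor(t[, 1], seq_len(k)),
                               factor(t[, 2], seq_len(k))))
      }
    }
    M
  }
  normalise <- function(M) {
    rs <- rowSums(M)
    M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
    M
  }
  obs <- normalise(directed_counts(cn_labels))
  perms <- with_seed(substream_seed(seed, "cnprox"), {
    lapply(seq_len(n_perm), function(p)
      normalise(directed_counts(lapply(cn_labels, sample))))
  })
  arr <- simplify2array(perms)
  mu <- apply(arr, c(1, 2), mean)
  sd_ <- apply(arr, c(1, 2), stats::sd)
  score <- (obs - mu) / ifelse(sd_ > 0, sd_, 1)
  dimnames(score) <- dimnames(obs)
  list(score = score, observed = obs, null_mean = mu, null_sd = sd_)
}

#' Correlate CN abundance with a per-case covariate
#'
#' Both variables are tested for normality (Shapiro-Wilk at alpha = 0.05);
#' Pearson correlation when both pass, Spearman otherwise. A least-squares
#' line is returned for plotting.
#'
#' @param abundance numeric vector (e.g. one CN's case-level abundance).
#' @param covariate numeric vector of the same length (e.g. growth rate).
#' @param alpha_norm normality gate level (default 0.05).
#' @return list with method ("pearson"/"spearman"), estimate, p_value,
#'   shapiro_p (both variables), intercept, slope, n.
#' @export
correlate_with_covariate <- function(abundance, covariate, alpha_norm = 0.05) {
  ok <- is.finite(abundance) & is.finite(covariate)
  x <- abundance[ok]; y <- covariate[ok]
  if (length(x) < 4) stop("need at least 4 cases", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in abundance or covariate", call. = FALSE)
  sw <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  method <- if (all(sw > alpha_norm)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  fit <- stats::lm(y ~ x)
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, shapiro_p = sw,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), n = length(x))
}
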