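# Synthetic tissue generator.
#
# Produces multi-population point patterns in rectangular ROIs with the kinds
# of spatial organisation seen in schwannoma histology: dense organised
# (Antoni A-like) regions with perivascular niches and TAM/T-cell aggregates
# that spatially exclude Schwann cells, and sparse (Antoni B-like) regions
# where T cells intermix with PD-L1+ Schwann cells. Marker intensities are
# drawn per population with multiplicative log-normal noise and per-case batch
# effects; expression counts for receptor-ligand analysis are negative
# binomial with planted fold-changes.

#' Describe one cell population of a synthetic tissue
#'
#' @param name population label.
#' @param parent_group one of "Schwann", "Myeloid", "Lymphoid", "Vascular",
#'   "Other".
#' @param density expected cells per mm^2 (>= 0).
#' @param marker_profile named non-negative numeric vector of mean raw marker
#'   intensities.
#' @param dispersion sdlog of the multiplicative log-normal intensity noise.
#' @param placement one of "CSR" (homogeneous Poisson), "ThomasCluster",
#'   "Perivascular", "CoClusterWith".
#' @param placement_params list of placement parameters: for "ThomasCluster",
#'   \code{mean_offspring} and \code{sigma_um}; for "CoClusterWith",
#'   \code{partner} (population name) and optional \code{strength} in [0,1].
#' @return an object of class \code{population_spec}.
#' @export
population_spec <- function(name, parent_group, density, marker_profile,
                            dispersion = 0.15, placement = "CSR",
                            placement_params = list()) {
  parent_group <- match.arg(parent_group,
                            c("Schwann", "Myeloid", "Lymphoid", "Vascular", "Other"))
  placement <- match.arg(placement,
                         c("CSR", "ThomasCluster", "Perivascular", "CoClusterWith"))
  assert_scalar_num(density, "density")
  if (density < 0) stop("'density' must be >= 0", call. = FALSE)
  if (is.null(names(marker_profile)) || any(marker_profile < 0))
    stop("'marker_profile' must be a named non-negative vector", call. = FALSE)
  structure(list(name = name, parent_group = parent_group, density = density,
                 marker_profile = marker_profile, dispersion = dispersion,
                 placement = placement, placement_params = placement_params),
            class = "population_spec")
}

#' Describe a vessel as a polyline with a perivascular halo
#'
#' @param polyline two-column matrix of control points (x, y in um).
#' @param halo_radius_um radius (um) within which perivascular populations are
#'   placed.
#' @return an object of class \code{vessel_spec}.
#' @export
vessel_spec <- function(polyline, halo_radius_um = 30) {
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L)
    stop("'polyline' must be an n x 2 matrix with n >= 2", call. = FALSE)
  assert_scalar_num(halo_radius_um, "halo_radius_um", positive = TRUE)
  structure(list(polyline = polyline, halo_radius_um = halo_radius_um),
            class = "vessel_spec")
}

#' Assemble a tissue specification for one ROI class
#'
#' The specification, together with its seed, fully determines the generated
#' cell table: identical specs give byte-identical output.
#'
#' @param roi_width_um,roi_height_um ROI extent in um (default 1000 x 1000).
#' @param region_class "AntoniA", "AntoniB" or "Mixed".
#' @param populations list of \code{\link{population_spec}} objects.
#' @param vessels list of \code{\link{vessel_spec}} objects.
#' @param planted_pairs list of \code{list(a, b, strength)} entries: both named
#'   populations place a fraction \code{strength} of their cells as offspring
#'   of shared Thomas-process parents, guaranteeing positive short-range
#'   cross-correlation.
#' @param batch_effects named list (by case id) of named multiplier vectors
#'   (by marker); see \code{\link{make_batch_effects}}.
#' @param seed integer root seed.
#' @return an object of class \code{tissue_spec}.
#' @export
tissue_spec <- function(roi_width_um = 1000, roi_height_um = 1000,
                        region_class = c("AntoniA", "AntoniB", "Mixed"),
                        populations = list(), vessels = list(),
                        planted_pairs = list(), batch_effects = NULL,
                        seed = 1L) {
  region_class <- match.arg(region_class)
  assert_scalar_num(roi_width_um, "roi_width_um", positive = TRUE)
  assert_scalar_num(roi_height_um, "roi_height_um", positive = TRUE)
  for (p in populations)
    if (!inherits(p, "population_spec")) stop("populations must be population_spec objects")
  for (v in vessels) {
    if (!inherits(v, "vessel_spec")) stop("vessels must be vessel_spec objects")
    if (any(v$polyline[, 1] < 0 | v$polyline[, 1] > roi_width_um |
            v$polyline[, 2] < 0 | v$polyline[, 2] > roi_height_um))
      stop("vessel polyline must lie inside the ROI", call. = FALSE)
  }
  pop_names <- vapply(populations, `[[`, "", "name")
  for (pp in planted_pairs) {
    if (!all(c(pp$a, pp$b) %in% pop_names))
      stop("planted pair references unknown population", call. = FALSE)
  }
  structure(list(roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                 region_class = region_class, populations = populations,
                 vessels = vessels, planted_pairs = planted_pairs,
                 batch_effects = batch_effects, seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Draw per-case multiplicative batch effects
#'
#' Batch effects are log-normal multipliers per (case, marker), the
#' intensity-scale artefact that batch-balanced graph construction is meant to
#' absorb.
#'
#' @param case_ids character vector of case identifiers.
#' @param markers character vector of marker names.
#' @param sdlog sdlog of the log-normal multiplier (default 0.25).
#' @param seed integer seed.
#' @return named list (case) of named numeric vectors (marker).
#' @export
make_batch_effects <- function(case_ids, markers, sdlog = 0.25, seed = 1L) {
  with_seed(substream_seed(seed, "batch"), {
    out <- lapply(case_ids, function(cid) {
      stats::setNames(exp(stats::rnorm(length(markers), 0, sdlog)), markers)
    })
    names(out) <- case_ids
    out
  })
}

# -- placement primitives ----------------------------------------------------

place_csr <- function(n, W, H) {
  cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H))
}

# Thomas process: Poisson parents (window expanded by 4*sigma), Poisson(mu)
# offspring with isotropic Gaussian displacement, clipped to the window.
place_thomas <- function(kappa_per_mm2, mu, sigma, W, H) {
  pad <- 4 * sigma
  area_mm2 <- (W + 2 * pad) * (H + 2 * pad) / 1e6
  n_par <- stats::rpois(1, kappa_per_mm2 * area_mm2)
  if (n_par == 0) return(cbind(x = numeric(), y = numeric()))
  px <- stats::runif(n_par, -pad, W + pad)
  py <- stats::runif(n_par, -pad, H + pad)
  n_off <- stats::rpois(n_par, mu)
  idx <- rep.int(seq_len(n_par), n_off)
  x <- px[idx] + stats::rnorm(length(idx), 0, sigma)
  y <- py[idx] + stats::rnorm(length(idx), 0, sigma)
  keep <- x >= 0 & x < W & y >= 0 & y < H
  cbind(x = x[keep], y = y[keep])
}

# n points uniform within halo_radius of any vessel polyline, by rejection.
place_perivascular <- function(n, vessels, W, H, max_tries = 500L) {
  if (length(vessels) == 0)
    stop("perivascular placement requires at least one vessel", call. = FALSE)
  segs <- do.call(rbind, lapply(seq_along(vessels), function(vi) {
    pl <- vessels[[vi]]$polyline
    cbind(x0 = pl[-nrow(pl), 1], y0 = pl[-nrow(pl), 2],
          x1 = pl[-1, 1], y1 = pl[-1, 2], halo = vessels[[vi]]$halo_radius_um)
  }))
  len <- sqrt((segs[, "x1"] - segs[, "x0"])^2 + (segs[, "y1"] - segs[, "y0"])^2)
  if (all(len == 0)) stop("degenerate vessel polyline", call. = FALSE)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  for (try in seq_len(max_tries)) {
    if (got >= n) break
    m <- n - got
    si <- sample.int(nrow(segs), m, replace = TRUE, prob = len)
    t <- stats::runif(m)
    cx <- segs[si, "x0"] + t * (segs[si, "x1"] - segs[si, "x0"])
    cy <- segs[si, "y0"] + t * (segs[si, "y1"] - segs[si, "y0"])
    r <- segs[si, "halo"] * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    x <- cx + r * cos(th); y <- cy + r * sin(th)
    keep <- x >= 0 & x < W & y >= 0 & y < H
    k <- sum(keep)
    if (k > 0) {
      out[got + seq_len(k), ] <- cbind(x[keep], y[keep])
      got <- got + k
    }
  }
  if (got < n)
    stop("perivascular rejection sampling failed: vessels and halo leave too little of the window", call. = FALSE)
  colnames(out) <- c("x", "y")
  out
}

#' Generate the cells of one synthetic ROI
#'
#' Places every population according to its rule (complete spatial randomness,
#' Thomas cluster process, perivascular halo, or shared-parent co-clustering
#' for planted pairs), then draws raw marker intensities from each
#' population's profile with multiplicative log-normal noise and the case's
#' batch effect. All randomness derives from the spec seed through named
#' substreams keyed by \code{roi_id}, so output is reproducible.
#'
#' @param spec a \code{\link{tissue_spec}}.
#' @param roi_id,case_id identifiers stamped onto every cell.
#' @return a cell table (data.frame) with columns cell_id, roi_id, case_id,
#'   x_um, y_um, region, population, parent_group and one column per marker.
#' @export
generate_roi <- function(spec, roi_id = "ROI1", case_id = "case1") {
  stopifnot(inherits(spec, "tissue_spec"))
  W <- spec$roi_width_um; H <- spec$roi_height_um
  area_mm2 <- W * H / 1e6
  markers <- Reduce(union, lapply(spec$populations, function(p) names(p$marker_profile)))
  if (length(spec$populations) == 0) return(empty_cell_table())

  # populations drawn into planted co-cluster pairs, with strengths
  cocluster <- list()
  for (pp in spec$planted_pairs) {
    s <- pp$strength %||% 0.8
    key <- paste(pp$a, pp$b, sep = "|")
    cocluster[[key]] <- list(members = c(pp$a, pp$b), strength = s,
                             sigma = pp$sigma_um %||% 15,
                             kappa = pp$kappa_per_mm2 %||% 10)
  }
  for (p in spec$populations) {
    if (p$placement == "CoClusterWith") {
      partner <- p$placement_params$partner
      if (is.null(partner)) stop("CoClusterWith placement needs a 'partner'", call. = FALSE)
      key <- paste(p$name, partner, sep = "|")
      cocluster[[key]] <- list(members = c(p$name, partner),
                               strength = p$placement_params$strength %||% 0.8,
                               sigma = p$placement_params$sigma_um %||% 15,
                               kappa = p$placement_params$kappa_per_mm2 %||% 10)
    }
  }
  # population -> its co-cluster entry (first match wins)
  co_of <- list()
  for (key in names(cocluster))
    for (m in cocluster[[key]]$members)
      if (is.null(co_of[[m]])) co_of[[m]] <- key

  placed <- with_seed(substream_seed(spec$seed, paste0("placement:", roi_id)), {
    # shared parents per co-cluster pair
    parents <- lapply(cocluster, function(cc) {
      pad <- 4 * cc$sigma
      n_par <- stats::rpois(1, cc$kappa * (W + 2 * pad) * (H + 2 * pad) / 1e6)
      cbind(x = stats::runif(max(n_par, 1L), -pad, W + pad),
            y = stats::runif(max(n_par, 1L), -pad, H + pad))
    })
    lapply(spec$populations, function(p) {
      lambda <- p$density * area_mm2
      if (lambda > 2e6)
        stop(sprintf("population '%s': density too high for rejection sampling", p$name),
             call. = FALSE)
      key <- co_of[[p$name]]
      if (!is.null(key)) {
        cc <- cocluster[[key]]
        n <- stats::rpois(1, lambda)
        n_cl <- stats::rbinom(1, n, cc$strength)
        par <- parents[[key]]
        pts_cl <- if (n_cl > 0) {
          pi <- sample.int(nrow(par), n_cl, replace = TRUE)
          x <- par[pi, 1] + stats::rnorm(n_cl, 0, cc$sigma)
          y <- par[pi, 2] + stats::rnorm(n_cl, 0, cc$sigma)
          keep <- x >= 0 & x < W & y >= 0 & y < H
          cbind(x = x[keep], y = y[keep])
        } else cbind(x = numeric(), y = numeric())
        rbind(pts_cl, place_csr(n - n_cl, W, H))
      } else if (p$placement == "CSR") {
        place_csr(stats::rpois(1, lambda), W, H)
      } else if (p$placement == "ThomasCluster") {
        mu <- p$placement_params$mean_offspring %||% 20
        sigma <- p$placement_params$sigma_um %||% 25
        place_thomas(p$density / mu, mu, sigma, W, H)
      } else if (p$placement == "Perivascular") {
        place_perivascular(stats::rpois(1, lambda), spec$vessels, W, H)
      }
    })
  })

  n_per <- vapply(placed, nrow, 0L)
  n_tot <- sum(n_per)
  pop <- rep(vapply(spec$populations, `[[`, "", "name"), n_per)
  grp <- rep(vapply(spec$populations, `[[`, "", "parent_group"), n_per)
  xy <- do.call(rbind, placed)

  cells <- data.frame(cell_id = seq_len(n_tot), roi_id = roi_id,
                      case_id = case_id,
                      x_um = if (n_tot) xy[, 1] else numeric(),
                      y_um = if (n_tot) xy[, 2] else numeric(),
                      region = spec$region_class, population = pop,
                      parent_group = grp, stringsAsFactors = FALSE)

  batch <- spec$batch_effects[[case_id]]
  intens <- with_seed(substream_seed(spec$seed, paste0("intensity:", roi_id)), {
    M <- matrix(0, n_tot, length(markers), dimnames = list(NULL, markers))
    offset <- 0L
    for (pi in seq_along(spec$populations)) {
      p <- spec$populations[[pi]]
      if (n_per[pi] == 0L) next
      rows <- offset + seq_len(n_per[pi])
      prof <- stats::setNames(numeric(length(markers)), markers)
      prof[names(p$marker_profile)] <- p$marker_profile
      noise <- matrix(exp(stats::rnorm(n_per[pi] * length(markers), 0, p$dispersion)),
                      n_per[pi], length(markers))
      M[rows, ] <- noise * rep(prof, each = n_per[pi])
      offset <- offset + n_per[pi]
    }
    if (!is.null(batch)) {
      b <- stats::setNames(rep(1, length(markers)), markers)
      b[names(batch)] <- batch
      M <- M * rep(b, each = n_tot)
    }
    M
  })
  if (n_tot == 0) return(empty_cell_table(markers))
  cbind(cells, as.data.frame(intens))
}

#' Render a cell table into a channel stack and matching label mask
#'
#' Each cell becomes a hard disc of radius \code{cell_radius_um} at 1 um/pixel
#' (no point-spread blur, so quantification round-trips are exact). Where
#' discs overlap, channel intensities are summed and the mask label is
#' resolved to the nearest cell centre (ties to the lower cell_id). Pixel
#' (row r, col c) has its centre at (c - 0.5, r - 0.5) um, origin top-left,
#' y increasing downward.
#'
#' @param cells a cell table with x_um, y_um and marker columns.
#' @param width_um,height_um image extent in um (pixels = um).
#' @param markers marker columns to render (default all).
#' @param cell_radius_um disc radius in um.
#' @return list with \code{stack} (height x width x markers array),
#'   \code{mask} (integer matrix, 0 background, cell_id labels) and
#'   \code{markers}.
#' @export
generate_channel_stack <- function(cells, width_um, height_um,
                                   markers = NULL, cell_radius_um = 3) {
  W <- as.integer(width_um); H <- as.integer(height_um)
  if (is.null(markers)) markers <- marker_cols(cells)
  stack <- array(0, dim = c(H, W, length(markers)),
                 dimnames = list(NULL, NULL, markers))
  mask <- matrix(0L, H, W)
  if (nrow(cells) == 0) return(list(stack = stack, mask = mask, markers = markers))
  if (any(cells$x_um < 0 | cells$x_um > W | cells$y_um < 0 | cells$y_um > H))
    stop("cells fall outside the image bounds", call. = FALSE)
  bestd <- matrix(Inf, H, W)
  r <- cell_radius_um
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]
    cset <- max(1L, ceiling(cx - r)):min(W, floor(cx + r) + 1L)
    rset <- max(1L, ceiling(cy - r)):min(H, floor(cy + r) + 1L)
    pcx <- cset - 0.5; pcy <- rset - 0.5
    d2 <- outer((pcy - cy)^2, (pcx - cx)^2, `+`)
    inside <- d2 <= r^2
    if (!any(inside)) next
    rows <- rep(rset, times = length(cset))[inside]
    cols <- rep(cset, each = length(rset))[inside]
    lin <- rows + (cols - 1L) * H
    for (mi in seq_along(markers)) {
      off <- (mi - 1L) * H * W
      stack[off + lin] <- stack[off + lin] + cells[[markers[mi]]][i]
    }
    upd <- d2[inside] < bestd[lin]  # strict: equal distance keeps lower id
    mask[lin[upd]] <- cells$cell_id[i]
    bestd[lin[upd]] <- d2[inside][upd]
  }
  list(stack = stack, mask = mask, markers = markers)
}

#' Generate labelled negative-binomial expression counts with planted pairs
#'
#' Baseline genes are exchangeable across populations; for each planted
#' receptor-ligand pair the ligand gene is elevated by \code{fold} in its
#' sender population and the receptor gene by \code{fold} in its receiver
#' population.
#'
#' @param populations character vector of population names.
#' @param lr_pairs data.frame with columns pair_id, ligand, receptor, sender,
#'   receiver, fold (fold > 0; fold = 1 plants no effect).
#' @param n_cells_per_pop cells per population.
#' @param n_background_genes exchangeable genes in addition to the pair genes.
#' @param base_mu baseline negative-binomial mean per gene.
#' @param size negative-binomial size (dispersion) parameter.
#' @param seed integer seed.
#' @return list with \code{counts} (genes x cells integer matrix),
#'   \code{labels} (population per cell) and \code{genes}.
#' @export
generate_expression_counts <- function(populations, lr_pairs,
                                       n_cells_per_pop = 200,
                                       n_background_genes = 50,
                                       base_mu = 2, size = 2, seed = 1L) {
  if (nrow(lr_pairs) > 0) {
    if (any(lr_pairs$fold <= 0)) stop("fold-change must be > 0", call. = FALSE)
    bad <- !(lr_pairs$sender %in% populations) | !(lr_pairs$receiver %in% populations)
    if (any(bad)) stop("planted pair references unknown population", call. = FALSE)
  }
  pair_genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  genes <- c(pair_genes, sprintf("BG%03d", seq_len(n_background_genes)))
  labels <- rep(populations, each = n_cells_per_pop)
  n <- length(labels)
  counts <- matrix(0L, length(genes), n, dimnames = list(genes, NULL))
  if (n == 0) return(list(counts = counts, labels = labels, genes = genes))
  with_seed(substream_seed(seed, "counts"), {
    mu <- matrix(base_mu, length(genes), n, dimnames = list(genes, NULL))
    for (k in seq_len(nrow(lr_pairs))) {
      mu[lr_pairs$ligand[k], labels == lr_pairs$sender[k]] <-
        base_mu * lr_pairs$fold[k]
      mu[lr_pairs$receptor[k], labels == lr_pairs$receiver[k]] <-
        base_mu * lr_pairs$fold[k]
    }
    counts[] <- stats::rnbinom(length(mu), size = size, mu = mu)
  })
  list(counts = counts, labels = labels, genes = genes)
}

#' Library-size normalise and log-transform a count matrix
#'
#' Counts are scaled so every cell has the median library size, then
#' log1p-transformed — the conventional preprocessing for mean-expression
#' receptor-ligand scoring.
#'
#' @param counts genes x cells count matrix.
#' @return matrix of normalised log counts.
#' @export
normalize_counts <- function(counts) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log1p(t(t(counts) * (stats::median(lib) / lib)))
}

#' Perturb a label mask to emulate imperfect manual segmentation
#'
#' Each object is independently shifted, eroded or dilated by up to
#' \code{perturbation} pixels (labels preserved). Objects that vanish under
#' erosion are recorded in the \code{"vanished"} attribute. Where perturbed
#' objects collide, the lower label wins.
#'
#' @param mask integer label matrix.
#' @param perturbation maximum perturbation in pixels (>= 0).
#' @param seed integer seed.
#' @return a perturbed label mask with attribute \code{vanished}.
#' @export
generate_mask_pair <- function(mask, perturbation, seed = 1L) {
  stopifnot(perturbation >= 0)
  if (perturbation == 0) {
    attr(mask, "vanished") <- integer()
    return(mask)
  }
  H <- nrow(mask); W <- ncol(mask)
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  out <- matrix(0L, H, W)
  vanished <- integer()
  with_seed(substream_seed(seed, "maskperturb"), {
    for (lb in labs) {
      idx <- which(mask == lb)
      rows <- ((idx - 1L) %% H) + 1L
      cols <- ((idx - 1L) %/% H) + 1L
      op <- sample(c("shift", "erode", "dilate"), 1)
      k <- sample.int(perturbation, 1)
      if (op == "shift") {
        dr <- sample(c(-k, k), 1); dc <- sample(c(-k, k), 1)
        rows <- rows + dr; cols <- cols + dc
      } else if (op == "erode") {
        # keep pixels at Chebyshev depth > k from the object boundary
        pix <- paste(rows, cols)
        keep <- rep(TRUE, length(rows))
        for (i in seq_along(rows)) {
          rr <- (rows[i] - k):(rows[i] + k)
          cc <- (cols[i] - k):(cols[i] + k)
          if (!all(paste(rep(rr, times = length(cc)), rep(cc, each = length(rr))) %in% pix))
            keep[i] <- FALSE
        }
        rows <- rows[keep]; cols <- cols[keep]
      } else {
        grid <- expand.grid(dr = -k:k, dc = -k:k)
        rows <- rep(rows, each = nrow(grid)) + grid$dr
        cols <- rep(cols, each = nrow(grid)) + grid$dc
        dup <- duplicated(cbind(rows, cols))
        rows <- rows[!dup]; cols <- cols[!dup]
      }
      ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
      rows <- rows[ok]; cols <- cols[ok]
      if (length(rows) == 0) { vanished <- c(vanished, lb); next }
      lin <- rows + (cols - 1L) * H
      free <- out[lin] == 0L
      out[lin[free]] <- lb
      if (!any(free)) vanished <- c(vanished, lb)
    }
  })
  attr(out, "vanished") <- vanished
  out
}
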