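# Per-cell quantification from a nuclear label mask plus channel stack.
#
# Convention used throughout: images are matrices indexed [row, col] with the
# origin at the top-left; pixel (r, c) has its centre at (c - 0.5, r - 0.5) um
# and y increases downward. Pixel pitch is 1 um.

#' Quantify cells by expanding nuclear labels and averaging channel intensity
#'
#' Each nuclear label is dilated \code{expansion_px} times with an
#' 8-connected (square) structuring element; a contested background pixel is
#' assigned to the contender whose nuclear centroid is nearest (ties to the
#' lower label). Per-marker means are taken over the expanded region and the
#' centroid is the mean of the expanded-region pixel centres.
#'
#' @param mask integer label matrix (0 = background).
#' @param stack height x width x markers array, or a list as returned by
#'   \code{\link{generate_channel_stack}}.
#' @param expansion_px number of one-pixel expansion steps (default 1).
#' @param roi_id,case_id identifiers stamped onto the output rows.
#' @return a cell table with cell_id, x_um, y_um, area_px and one mean-intensity
#'   column per marker; one row per mask label, ordered by label.
#' @export
extract_cells <- function(mask, stack, expansion_px = 1L,
                          roi_id = "ROI1", case_id = "case1") {
  if (is.list(stack)) stack <- stack$stack
  stopifnot(expansion_px >= 0)
  if (length(dim(stack)) != 3L || !all(dim(stack)[1:2] == dim(mask)))
    stop("mask and stack shapes do not agree", call. = FALSE)
  markers <- dimnames(stack)[[3]] %||% sprintf("ch%d", seq_len(dim(stack)[3]))
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (length(labs) == 0) {
    out <- data.frame(cell_id = integer(), roi_id = character(),
                      case_id = character(), x_um = numeric(), y_um = numeric(),
                      area_px = integer())
    for (m in markers) out[[m]] <- numeric()
    return(out)
  }
  H <- nrow(mask); W <- ncol(mask)
  # nuclear centroids (of the un-expanded mask), for the contested-pixel rule
  idx0 <- which(mask > 0)
  lab0 <- mask[idx0]
  r0 <- ((idx0 - 1L) %% H) + 1L
  c0 <- ((idx0 - 1L) %/% H) + 1L
  cent_x <- tapply(c0 - 0.5, lab0, mean)
  cent_y <- tapply(r0 - 0.5, lab0, mean)
  cx <- stats::setNames(rep(NA_real_, max(labs)), NULL); cx[labs] <- cent_x[as.character(labs)]
  cy <- rep(NA_real_, max(labs)); cy[labs] <- cent_y[as.character(labs)]

  expanded <- expand_labels(mask, expansion_px, cx, cy)

  idx <- which(expanded > 0)
  lab <- expanded[idx]
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(lab, nbins = max(labs))[labs]
  f <- factor(lab, levels = labs)
  x_um <- as.numeric(tapply(cc - 0.5, f, mean))
  y_um <- as.numeric(tapply(rr - 0.5, f, mean))
  out <- data.frame(cell_id = labs, roi_id = roi_id, case_id = case_id,
                    x_um = x_um, y_um = y_um, area_px = area,
                    stringsAsFactors = FALSE)
  HW <- H * W
  for (mi in seq_along(markers)) {
    v <- stack[(mi - 1L) * HW + idx]
    out[[markers[mi]]] <- as.numeric(tapply(v, f, mean))
  }
  out
}

# Dilate every label `steps` times with the 8-connected structuring element.
# A pixel reached by several labels in the same step goes to the label whose
# nuclear centroid (cx, cy indexed by label) is nearest; ties -> lower label.
expand_labels <- function(mask, steps, cx, cy) {
  if (steps == 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  cur <- mask
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in seq_len(steps)) {
    bestlab <- matrix(0L, H, W)
    bestd <- matrix(Inf, H, W)
    for (sh in shifts) {
      dr <- sh[1]; dc <- sh[2]
      # source rows/cols shifted into place
      src <- matrix(0L, H, W)
      rs <- max(1, 1 + dr):min(H, H + dr)   # destination rows
      cs <- max(1, 1 + dc):min(W, W + dc)   # destination cols
      src[rs, cs] <- cur[rs - dr, cs - dc]
      cand <- which(src > 0L & cur == 0L)
      if (length(cand) == 0) next
      lb <- src[cand]
      pr <- ((cand - 1L) %% H) + 1L
      pc <- ((cand - 1L) %/% H) + 1L
      d <- (pc - 0.5 - cx[lb])^2 + (pr - 0.5 - cy[lb])^2
      better <- d < bestd[cand] | (d == bestd[cand] & lb < bestlab[cand])
      upd <- cand[better]
      bestlab[upd] <- lb[better]
      bestd[upd] <- d[better]
    }
    new <- bestlab > 0L
    cur[new] <- bestlab[new]
  }
  cur
}

#' Segmentation QC via per-cell Jaccard indices
#'
#' Samples \code{n_cells_per_roi} cells from the automatic mask (without
#' replacement; all cells if fewer are present), matches each to the manual
#' object with maximal pixel overlap, and reports J = |intersection| / |union|.
#' A sampled cell with no overlapping manual object gets J = 0 and is flagged.
#'
#' @param auto,manual integer label masks of the same shape.
#' @param n_cells_per_roi number of cells to sample (default 50).
#' @param seed integer seed for the sample.
#' @param threshold reporting threshold for the "fraction above" summary
#'   (default 0.5).
#' @return list with \code{per_cell} (data.frame: cell_id, matched_label,
#'   jaccard, unmatched), \code{mean_jaccard}, \code{frac_above},
#'   \code{threshold}, \code{n_sampled} and \code{all_used} (TRUE when the
#'   mask had fewer cells than requested).
#' @export
jaccard_qc <- function(auto, manual, n_cells_per_roi = 50L, seed = 1L,
                       threshold = 0.5) {
  if (!all(dim(auto) == dim(manual)))
    stop("masks must share a shape", call. = FALSE)
  labs <- sort(setdiff(unique(as.vector(auto)), 0L))
  all_used <- length(labs) <= n_cells_per_roi
  sel <- if (all_used) labs else
    with_seed(substream_seed(seed, "jaccard"), sort(sample(labs, n_cells_per_roi)))
  res <- lapply(sel, function(lb) {
    pa <- which(auto == lb)
    ov <- manual[pa]
    ov <- ov[ov > 0L]
    if (length(ov) == 0)
      return(data.frame(cell_id = lb, matched_label = NA_integer_,
                        jaccard = 0, unmatched = TRUE))
    ml <- as.integer(names(which.max(table(ov))))
    pm <- which(manual == ml)
    inter <- length(intersect(pa, pm))
    data.frame(cell_id = lb, matched_label = ml,
               jaccard = inter / (length(pa) + length(pm) - inter),
               unmatched = FALSE)
  })
  per_cell <- do.call(rbind, res) %||%
    data.frame(cell_id = integer(), matched_label = integer(),
               jaccard = numeric(), unmatched = logical())
  list(per_cell = per_cell,
       mean_jaccard = if (nrow(per_cell)) mean(per_cell$jaccard) else NA_real_,
       frac_above = if (nrow(per_cell)) mean(per_cell$jaccard > threshold) else NA_real_,
       threshold = threshold, n_sampled = nrow(per_cell), all_used = all_used)
}
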