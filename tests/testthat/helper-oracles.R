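# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (double loops, enumeration) and share no code
# with the implementation paths they check.

# Brute-force cross-PCF: double loop over cells, annulus areas by dense grid.
oracle_cross_pcf <- function(cells, type_a, type_b, r_max, dr, W, H,
                             edge_correction = TRUE) {
  breaks <- seq(0, r_max, by = dr)
  ia <- which(cells$population == type_a)
  ib <- which(cells$population == type_b)
  rho <- length(ib) / (W * H)
  g <- numeric(length(breaks) - 1)
  for (k in seq_along(g)) {
    acc <- 0
    for (i in ia) {
      cnt <- 0
      for (j in ib) {
        if (i == j) next
        d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2)
        if (d >= breaks[k] && d < breaks[k + 1]) cnt <- cnt + 1
      }
      if (edge_correction) {
        a <- oracle_circle_area(cells$x_um[i], cells$y_um[i], breaks[k + 1], W, H) -
          oracle_circle_area(cells$x_um[i], cells$y_um[i], breaks[k], W, H)
      } else {
        a <- pi * (breaks[k + 1]^2 - breaks[k]^2)
      }
      acc <- acc + cnt / (rho * a)
    }
    g[k] <- acc / length(ia)
  }
  g
}

# Disc-in-rectangle area by grid summation (independent of the geometric
# formula); resolution chosen so the boundary error is < 0.15 um^2 for the
# window sizes used in tests.
oracle_circle_area <- function(cx, cy, r, W, H, n = 1500) {
  if (r <= 0) return(0)
  xs <- seq(0.5 * W / n, W - 0.5 * W / n, length.out = n)
  ys <- seq(0.5 * H / n, H - 0.5 * H / n, length.out = n)
  mean(outer((xs - cx)^2, (ys - cy)^2, `+`) <= r^2) * W * H
}

# Pair-counting Fowlkes-Mallows by explicit enumeration of all item pairs.
oracle_fmi <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) tp <- tp + 1
    else if (sa && !sb) fp <- fp + 1
    else if (!sa && sb) fn <- fn + 1
  }
  if (tp + fp == 0 || tp + fn == 0)
    return(if ((tp + fp) == (tp + fn)) 1 else 0)
  tp / sqrt((tp + fp) * (tp + fn))
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# A square cell of side `side` with top-left pixel (r0, c0) painted onto mask.
paint_square <- function(mask, r0, c0, side, label) {
  mask[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- label
  mask
}

# Uniformly random CSR ROI with two labels for null calibration.
csr_two_type_roi <- function(n_a = 100, n_b = 100, W = 1000, H = 1000) {
  data.frame(x_um = stats::runif(n_a + n_b, 0, W),
             y_um = stats::runif(n_a + n_b, 0, H),
             population = sample(rep(c("A", "B"), c(n_a, n_b))),
             roi_id = "roi1", stringsAsFactors = FALSE)
}

# One ROI with three vertical bands, each occupied by one population with an
# orthogonal (mutually equidistant) marker profile, separated by gaps wider
# than the spatial-graph trim. The planted neighbourhood truth is therefore
# exactly three compositions with no mixed boundary neighbourhoods. Returns
# cells plus the true domain of each cell.
planted_cn_roi <- function(n_per_band = 300, H = 900, noise = 0.12,
                           band_w = 260, gap = 60, baseline = 0.4) {
  mk <- paste0("M", 1:3)
  out <- list()
  for (b in 1:3) {
    x0 <- (b - 1) * (band_w + gap)
    x <- stats::runif(n_per_band, x0, x0 + band_w)
    y <- stats::runif(n_per_band, 0, H)
    # baseline well above zero so positivity truncation stays negligible and
    # per-band marker distributions are effectively Gaussian
    M <- matrix(stats::rnorm(n_per_band * 3, baseline, noise), n_per_band, 3,
                dimnames = list(NULL, mk))
    M[, b] <- M[, b] + 1
    out[[b]] <- cbind(data.frame(x_um = x, y_um = y,
                                 population = paste0("P", b),
                                 domain = b, stringsAsFactors = FALSE),
                      as.data.frame(pmax(M, 0)))
  }
  do.call(rbind, out)
}
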