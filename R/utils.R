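# Internal helpers: seed substreams, argument checks, small utilities.

#' Derive a reproducible sub-seed from a root seed and stream name
#'
#' All randomness in the package flows from one root seed through named
#' substreams so that stages (placement, intensity, counts, permutation) can be
#' re-run independently while remaining jointly reproducible. The derived seed
#' is a deterministic 31-bit hash of the root seed and the stream label.
#'
#' @param root_seed integer root seed.
#' @param stream character label of the substream.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
#' @examples
#' substream_seed(1L, "placement")
substream_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(root_seed) %% m
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647), expr)
}

# Shorthand validators ------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Columns of a cell table that are metadata rather than markers.
CELL_META_COLS <- c("cell_id", "roi_id", "case_id", "x_um", "y_um", "area_px",
                    "region", "population", "parent_group", "severity",
                    "treatment", "cn")

#' Marker column names of a cell table
#'
#' Every column that is not one of the reserved metadata columns is treated as
#' a marker intensity column.
#'
#' @param cells a cell table (data.frame).
#' @return character vector of marker names.
#' @export
marker_cols <- function(cells) {
  setdiff(colnames(cells), CELL_META_COLS)
}

# Empty cell table with the canonical schema plus the given marker columns.
empty_cell_table <- function(markers = character()) {
  base <- data.frame(cell_id = integer(), roi_id = character(),
                     case_id = character(), x_um = numeric(), y_um = numeric(),
                     region = character(), population = character(),
                     parent_group = character(), stringsAsFactors = FALSE)
  for (m in markers) base[[m]] <- numeric()
  base
}
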