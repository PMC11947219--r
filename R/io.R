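# External interfaces: TIFF images and masks, cell-table CSV, YAML rules.

#' Write a channel stack as a multi-page 16-bit TIFF
#'
#' Each marker becomes one page. Intensities are quantised to 16 bits using a
#' per-channel scale factor stored in a JSON sidecar (<path>.json) together
#' with the marker names; \code{\link{read_channel_stack}} restores the scale.
#'
#' @param stack height x width x markers array (or list from
#'   \code{\link{generate_channel_stack}}).
#' @param path output TIFF path.
#' @return invisibly, the sidecar metadata list.
#' @export
write_channel_stack <- function(stack, path) {
  if (is.list(stack)) stack <- stack$stack
  markers <- dimnames(stack)[[3]] %||% sprintf("ch%d", seq_len(dim(stack)[3]))
  scale <- vapply(seq_along(markers), function(i) {
    m <- max(stack[, , i])
    if (m <= 0) 1 else m
  }, 0)
  pages <- lapply(seq_along(markers), function(i) stack[, , i] / scale[i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(markers = markers, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(meta)
}

#' Read a channel stack written by \code{\link{write_channel_stack}}
#'
#' @param path TIFF path (expects the <path>.json sidecar).
#' @return height x width x markers array.
#' @export
read_channel_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)),
                 dimnames = list(NULL, NULL, meta$markers))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]] * meta$scale[i]
  stack
}

#' Write / read an integer label mask as single-page 16-bit TIFF
#'
#' Labels must fit in 16 bits (< 65536).
#'
#' @param mask integer label matrix.
#' @param path TIFF path.
#' @return (read) integer label matrix.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read a cell table as CSV
#'
#' @param cells cell table.
#' @param path CSV path.
#' @return (read) the cell table.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read population / group annotation rules from YAML
#'
#' @param path YAML file: top-level keys \code{group_rules} (group -> marker
#'   vector) and/or \code{population_rules} (population -> group/pos/neg).
#' @return list with group_rules and population_rules components.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  list(group_rules = y$group_rules, population_rules = y$population_rules)
}

#' Write a network as GraphML and an edge-list CSV
#'
#' @param network list from \code{\link{acn_network}}.
#' @param graphml_path,edges_path output paths (NULL skips either).
#' @return invisibly, the network.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.csv(network$edges, edges_path, row.names = FALSE)
  invisible(network)
}
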