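#' @useDynLib giantcell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rlnorm median quantile cor sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Labeled tissue raster
#'
#' The universal exchange format between pipeline stages: an integer-label
#' raster (0 = background) with a known isotropic pixel size. Rows run down
#' (y), columns right (x); pixel centers sit at integer coordinates, 0-based.
#'
#' @param labels integer matrix, values >= 0; 0 is background.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @return object of class `labeled_tissue` with fields `labels`,
#'   `pixel_size`, `cell_ids` (sorted positive labels present) and
#'   `border_ids` (labels with at least one pixel on the raster edge).
#' @export
labeled_tissue <- function(labels, pixel_size) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (is.double(labels)) {
    if (any(labels != round(labels))) stop("non-integer pixel data")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("non-integer pixel data")
  if (any(labels < 0L)) stop("labels must be >= 0")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) stop("degenerate input: raster is empty or all background")
  nr <- nrow(labels); nc <- ncol(labels)
  edge <- c(labels[1L, ], labels[nr, ], labels[, 1L], labels[, nc])
  structure(list(
    labels = labels,
    pixel_size = pixel_size,
    cell_ids = ids,
    border_ids = sort(unique(edge[edge > 0L]))
  ), class = "labeled_tissue")
}

#' @export
print.labeled_tissue <- function(x, ...) {
  cat(sprintf("labeled_tissue: %d x %d px (%.3g um/px), %d cells (%d at border), %.1f%% background\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              length(x$cell_ids), length(x$border_ids),
              100 * mean(x$labels == 0L)))
  invisible(x)
}

# pixel conservation check used after load and after every randomization
assert_pixel_conservation <- function(tissue) {
  n <- sum(tabulate(tissue$labels + 1L))
  stopifnot(n == length(tissue$labels))
  invisible(TRUE)
}

# linear pixel indices per label, as a named list
label_pixels <- function(labels, ids = NULL) {
  pos <- which(labels > 0L)
  px <- split(pos, labels[pos])
  if (!is.null(ids)) px <- px[as.character(ids)]
  px
}

#' Read / write labeled tissue rasters
#'
#' Supported formats, chosen by extension: `.csv`/`.tsv` (plain-text integer
#' matrix, no header) and `.png` (labels encoded bit-exactly over the RGB
#' channels as label = R*65536 + G*256 + B, supporting labels < 2^24).
#'
#' @param path file path; format inferred from the extension.
#' @param pixel_size micrometres per pixel of the stored raster.
#' @return `load_tissue` returns a [labeled_tissue()]; `save_tissue`
#'   invisibly returns `path`.
#' @export
load_tissue <- function(path, pixel_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  labels <- switch(ext,
    csv = as.matrix(read.csv(path, header = FALSE)),
    tsv = as.matrix(read.csv(path, header = FALSE, sep = "\t")),
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 2L) {
        round(img * 255)
      } else {
        round(img[, , 1] * 255) * 65536 + round(img[, , 2] * 255) * 256 + round(img[, , 3] * 255)
      }
    },
    stop("format error: unsupported extension '", ext, "'")
  )
  dimnames(labels) <- NULL
  if (any(labels != round(labels))) stop("format error: non-integer pixel data")
  storage.mode(labels) <- "integer"
  t <- labeled_tissue(labels, pixel_size)
  assert_pixel_conservation(t)
  t
}

#' @rdname load_tissue
#' @param tissue a [labeled_tissue()].
#' @export
save_tissue <- function(tissue, path) {
  ext <- tolower(tools::file_ext(path))
  lab <- tissue$labels
  if (ext == "csv") {
    write.table(lab, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (ext == "tsv") {
    write.table(lab, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else if (ext == "png") {
    if (max(lab) >= 2^24) stop("labels too large for PNG encoding")
    arr <- array(0, dim = c(nrow(lab), ncol(lab), 3))
    arr[, , 1] <- (lab %/% 65536) / 255
    arr[, , 2] <- ((lab %/% 256) %% 256) / 255
    arr[, , 3] <- (lab %% 256) / 255
    png::writePNG(arr, path)
  } else stop("format error: unsupported extension '", ext, "'")
  invisible(path)
}

#' Cell-adjacency graph of a labeled tissue
#'
#' Two cells are adjacent iff they share at least `min_contact` pixel-pair
#' contacts under the chosen pixel connectivity. The background is never a
#' node. The default `min_contact = 2` suppresses spurious single-corner
#' contacts.
#'
#' @param tissue a [labeled_tissue()].
#' @param connectivity 4 or 8.
#' @param min_contact minimum number of touching pixel pairs for an edge.
#' @return object of class `adjacency_graph`: list with `nodes` (all cell
#'   ids), `edges` (data.frame `a`, `b`, `weight` = shared-boundary contact
#'   count) and `graph` (the backing igraph object, vertex names = ids).
#' @export
build_adjacency <- function(tissue, connectivity = 4, min_contact = 2) {
  if (!connectivity %in% c(4, 8)) stop("config error: connectivity must be 4 or 8")
  if (min_contact < 1) stop("config error: min_contact must be >= 1")
  ct <- cpp_contacts(tissue$labels, as.integer(connectivity))
  keep <- ct$count >= min_contact
  edges <- data.frame(a = ct$a[keep], b = ct$b[keep], weight = ct$count[keep])
  adjacency_graph(tissue$cell_ids, edges)
}

# construct an adjacency_graph from nodes + edge table
adjacency_graph <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$a), to = as.character(edges$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d cells, %d contacts\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# neighbor ids of `id` in an adjacency_graph
graph_neighbors <- function(graph, id) {
  e <- graph$edges
  c(e$b[e$a == id], e$a[e$b == id])
}
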