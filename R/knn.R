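#' Construct a neighbor-graph object
#'
#' Internal container shared by exact KNN graphs and merged graphs. Rows are
#' stored as matrices in the object's canonical cell order; merged rows that
#' could not be filled to `k` neighbors carry `NA` padding at the tail.
#'
#' @param cell_ids Ordered character vector of cell ids.
#' @param k Neighbors per cell (self excluded).
#' @param idx Integer matrix n x k of neighbor positions (into `cell_ids`).
#' @param dist Numeric matrix n x k of distances, ascending within each row.
#' @param provenance Optional character matrix n x k tagging each edge with
#'   the object that contributed it (`"parent"` or `"child:<name>"`); its
#'   presence marks a merged graph.
#' @return A `neighbor_graph` (and `merged_graph` if provenance is present).
#' @keywords internal
new_neighbor_graph <- function(cell_ids, k, idx, dist, provenance = NULL) {
  stopifnot(length(cell_ids) == nrow(idx), ncol(idx) == k,
            identical(dim(idx), dim(dist)))
  dimnames(idx) <- dimnames(dist) <- NULL
  structure(
    list(cell_ids = cell_ids, k = as.integer(k), idx = idx, dist = dist,
         provenance = provenance),
    class = c(if (!is.null(provenance)) "merged_graph", "neighbor_graph")
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(if (inherits(x, "merged_graph")) "Merged neighbor graph"
      else "Neighbor graph",
      ": ", length(x$cell_ids), " cells, k = ", x$k, "\n", sep = "")
  short <- sum(rowSums(!is.na(x$idx)) < x$k)
  if (short) cat("  ", short, " row(s) shorter than k (NA padded)\n", sep = "")
  invisible(x)
}

#' Exact k-nearest-neighbor graph on a stored reduction
#'
#' Computes, for every cell, its `k` exact nearest neighbors (self excluded)
#' by Euclidean distance on the named low-dimensional reduction. Ties are
#' broken by cell order, so the result is fully deterministic.
#'
#' @param pi A `pi_obj`.
#' @param reduction Name of the reduction to use; defaults to the first one
#'   stored on the object.
#' @param k Number of neighbors (must be `< n_cells`).
#' @param metric Distance metric; only `"euclidean"` is supported.
#' @return A `neighbor_graph` with per-row distances sorted ascending.
#' @export
build_knn <- function(pi, reduction = NULL, k = 20, metric = "euclidean") {
  stopifnot(inherits(pi, "pi_obj"))
  metric <- match.arg(metric)
  if (!length(pi$reductions)) {
    stop("object has no reductions to build a KNN graph from", call. = FALSE)
  }
  if (is.null(reduction)) reduction <- names(pi$reductions)[1]
  if (!reduction %in% names(pi$reductions)) {
    stop("reduction '", reduction, "' not found; available: ",
         paste(names(pi$reductions), collapse = ", "), call. = FALSE)
  }
  x <- pi$reductions[[reduction]]
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k >= n) {
    stop("`k` (", k, ") must be smaller than the number of cells (", n, ")",
         call. = FALSE)
  }

  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  pos <- seq_len(n)
  for (i in pos) {
    o <- order(d[i, ], pos)   # explicit tie-break by cell order
    o <- o[o != i][seq_len(k)]
    idx[i, ] <- o
    dd[i, ] <- d[i, o]
  }
  new_neighbor_graph(pi$cells$cell_id, k, idx, dd)
}

# Per-row views dropping NA padding; used by the merge and embed stages.
graph_row <- function(g, i) {
  keep <- !is.na(g$idx[i, ])
  list(idx = g$idx[i, keep], dist = g$dist[i, keep],
       provenance = if (!is.null(g$provenance)) g$provenance[i, keep])
}

#' Export a neighbor graph as a sparse edge-list TSV
#'
#' One line per directed edge: `cell_id_from`, `cell_id_to`, `distance`
#' (full precision) and `provenance`. Rows are written in rank order.
#'
#' @param graph A `neighbor_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d", graph$k), con)
  writeLines("cell_id_from\tcell_id_to\tdistance\tprovenance", con)
  for (i in seq_along(graph$cell_ids)) {
    row <- graph_row(graph, i)
    if (!length(row$idx)) next
    prov <- if (is.null(row$provenance)) rep("parent", length(row$idx))
            else row$provenance
    writeLines(sprintf("%s\t%s\t%.17g\t%s", graph$cell_ids[i],
                       graph$cell_ids[row$idx], row$dist, prov), con)
  }
  invisible(path)
}

#' Read a neighbor graph written by [write_graph_tsv()]
#'
#' @param path Edge-list TSV.
#' @param cell_ids Canonical cell order of the owning object.
#' @return A `neighbor_graph` (merged if any edge has child provenance).
#' @export
read_graph_tsv <- function(path, cell_ids) {
  first <- readLines(path, n = 1L)
  k <- as.integer(sub("# k=", "", first, fixed = TRUE))
  edges <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                             colClasses = c("character", "character",
                                            "numeric", "character"))
  n <- length(cell_ids)
  idx <- matrix(NA_integer_, n, k)
  dd <- matrix(NA_real_, n, k)
  pv <- matrix(NA_character_, n, k)
  from <- match(edges$cell_id_from, cell_ids)
  to <- match(edges$cell_id_to, cell_ids)
  if (anyNA(from) || anyNA(to)) {
    stop("graph file references cell ids outside the object", call. = FALSE)
  }
  slot <- stats::ave(from, from, FUN = seq_along)
  idx[cbind(from, slot)] <- to
  dd[cbind(from, slot)] <- edges$distance
  pv[cbind(from, slot)] <- edges$provenance
  merged <- any(edges$provenance != "parent")
  new_neighbor_graph(cell_ids, k, idx, dd,
                     provenance = if (merged) pv)
}
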