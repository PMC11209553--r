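#' Silhouette-width report for an embedding
#'
#' Computes the standard silhouette width
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` for every cell, with Euclidean
#' distance on the supplied 2-D coordinates, where `a(i)` is the mean
#' distance to the cell's own cluster and `b(i)` the smallest mean distance
#' to any other cluster. Widths lie in `[-1, 1]`; higher means the labels
#' are better separated on the embedding. Cells in singleton clusters get
#' width 0 (with a warning), the usual convention.
#'
#' @param coords Numeric matrix, cells x d (typically d = 2).
#' @param labels Per-cell cluster labels, aligned with `coords` rows.
#' @param embedding Name recorded in the report.
#' @return A `silhouette_report`: `per_cluster` (cluster, n_cells,
#'   mean_sil), `overall` (mean over cells), and the per-cell `widths`.
#' @export
silhouette_report <- function(coords, labels, embedding = "embedding") {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(labels)) {
    stop("`labels` must align with the rows of `coords`", call. = FALSE)
  }
  f <- factor(labels)
  if (nlevels(f) < 2L) {
    stop("silhouette needs at least 2 distinct labels", call. = FALSE)
  }
  if (any(table(f) == 1L)) {
    warning("singleton cluster(s) present; their cells get width 0",
            call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(f), stats::dist(coords))
  widths <- sil[, "sil_width"]
  per_cluster <- data.frame(
    cluster = levels(f),
    n_cells = as.integer(table(f)),
    mean_sil = as.numeric(tapply(widths, f, mean)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(embedding = embedding, per_cluster = per_cluster,
                 overall = mean(widths), widths = widths),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat("Silhouette report on '", x$embedding, "': overall mean ",
      sprintf("%.3f", x$overall), "\n", sep = "")
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Compare cluster separation between two embeddings
#'
#' Computes silhouette reports for the same labels on two stored reductions
#' (e.g. the original UMAP and the re-projected one) and the per-cluster
#' deltas (after minus before). The comparison can be restricted to
#' subclustered or non-subclustered cells, the two regimes of interest: the
#' re-projection should sharpen subcluster labels while leaving untouched
#' clusters essentially unchanged.
#'
#' @param pi A `pi_obj` with both reductions.
#' @param before,after Reduction names.
#' @param level Label level passed to [resolve_labels()] (default leaf).
#' @param cells `"all"`, `"subclustered"` (cells covered by any child) or
#'   `"unsubclustered"`.
#' @return An `embedding_comparison`: the two reports plus a `deltas`
#'   data.frame (cluster, n_cells, before, after, delta, improved).
#' @export
compare_embeddings <- function(pi, before, after, level = "leaf",
                               cells = c("all", "subclustered",
                                         "unsubclustered")) {
  stopifnot(inherits(pi, "pi_obj"))
  cells <- match.arg(cells)
  for (nm in c(before, after)) {
    if (!nm %in% names(pi$reductions)) {
      stop("reduction '", nm, "' not found", call. = FALSE)
    }
  }
  labels <- resolve_labels(pi, level)$label
  keep <- rep(TRUE, length(labels))
  if (cells != "all") {
    sub_ids <- unique(unlist(child_cell_sets(pi), use.names = FALSE))
    in_sub <- pi$cells$cell_id %in% sub_ids
    keep <- if (cells == "subclustered") in_sub else !in_sub
  }
  if (sum(keep) < 3L) {
    stop("fewer than 3 cells selected for comparison", call. = FALSE)
  }
  b_coord <- pi$reductions[[before]][keep, , drop = FALSE]
  a_coord <- pi$reductions[[after]][keep, , drop = FALSE]
  if (nrow(b_coord) != nrow(a_coord)) {
    stop("embeddings '", before, "' and '", after,
         "' do not cover the same cells", call. = FALSE)
  }
  lab <- labels[keep]
  rb <- silhouette_report(b_coord, lab, embedding = before)
  ra <- silhouette_report(a_coord, lab, embedding = after)
  deltas <- merge(rb$per_cluster, ra$per_cluster,
                  by = c("cluster", "n_cells"),
                  suffixes = c("_before", "_after"))
  names(deltas)[names(deltas) == "mean_sil_before"] <- "before"
  names(deltas)[names(deltas) == "mean_sil_after"] <- "after"
  deltas$delta <- deltas$after - deltas$before
  deltas$improved <- deltas$delta > 0
  structure(list(before = rb, after = ra, deltas = deltas,
                 overall_delta = ra$overall - rb$overall, cells = cells),
            class = "embedding_comparison")
}

#' @export
print.embedding_comparison <- function(x, ...) {
  cat("Embedding comparison (", x$cells, " cells): overall delta ",
      sprintf("%+.3f", x$overall_delta), "\n", sep = "")
  print(x$deltas, row.names = FALSE)
  invisible(x)
}
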