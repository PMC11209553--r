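#' Create a post-integration (Pi) object
#'
#' The Pi object is the central container of the package: it couples one
#' clustering level's expression matrix, per-cell metadata, low-dimensional
#' reductions and analysis slots, and carries links to a parent object and to
#' named child subclustering objects. A hierarchy of Pi objects represents a
#' multi-level subcluster analysis (e.g. PBMC -> T cells -> CD4 memory).
#'
#' @param expression Sparse (or dense, coerced to sparse) nonnegative numeric
#'   matrix, genes x cells, with gene identifiers as row names.
#' @param cells A data.frame with one row per cell and at least the columns
#'   `cell_id` (unique), `sample_id`, `group`, `cluster`. Additional columns
#'   are kept as-is.
#' @param reductions Named list of per-cell coordinate matrices
#'   (cells x d, e.g. `pca`, `umap`). Rows must cover exactly the cells in
#'   `cells`; if row names are present they are used to align the order.
#'
#' @return An object of class `pi_obj` with empty analysis slots
#'   (`exp_freq`, `markers`, `ds`, `cell_prop`), no parent and no children.
#'   The input order of `cells` is preserved and is canonical for the object.
#' @export
#' @examples
#' expr <- Matrix::rsparsematrix(5, 8, density = 0.5)
#' expr@x <- abs(expr@x)
#' rownames(expr) <- paste0("g", 1:5)
#' cells <- data.frame(cell_id = paste0("c", 1:8), sample_id = "s1",
#'                     group = "A", cluster = rep(c("k1", "k2"), each = 4))
#' pi <- create_pi(expr, cells)
create_pi <- function(expression, cells, reductions = list()) {
  if (!is.data.frame(cells)) {
    stop("`cells` must be a data.frame of per-cell metadata", call. = FALSE)
  }
  required <- c("cell_id", "sample_id", "group", "cluster")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stop("cell metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  for (col in required) cells[[col]] <- as.character(cells[[col]])
  if (anyNA(cells[required])) {
    bad <- required[vapply(cells[required], anyNA, logical(1))]
    stop("cell metadata contains missing values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("cell_id values must be unique within one object", call. = FALSE)
  }

  expression <- as_sparse_counts(expression)
  if (is.null(rownames(expression))) {
    stop("`expression` must carry gene identifiers as row names", call. = FALSE)
  }
  if (ncol(expression) != nrow(cells)) {
    stop("structural mismatch in `expression`: ", ncol(expression),
         " columns but ", nrow(cells), " metadata rows", call. = FALSE)
  }
  if (length(expression@x) && min(expression@x) < 0) {
    stop("`expression` must be nonnegative", call. = FALSE)
  }
  colnames(expression) <- cells$cell_id

  if (length(reductions)) {
    if (is.null(names(reductions)) || any(!nzchar(names(reductions)))) {
      stop("`reductions` must be a named list", call. = FALSE)
    }
    reductions <- lapply(stats::setNames(names(reductions), names(reductions)),
      function(nm) align_reduction(reductions[[nm]], cells$cell_id, nm))
  } else {
    reductions <- list()
  }

  structure(
    list(
      expression = expression,
      cells = cells,
      reductions = reductions,
      neighbor_graphs = list(),
      exp_freq = NULL,
      markers = NULL,
      ds = NULL,
      cell_prop = list(),
      parent = NULL,
      children = list()
    ),
    class = "pi_obj"
  )
}

as_sparse_counts <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
}

align_reduction <- function(mat, cell_ids, name) {
  mat <- as.matrix(mat)
  if (nrow(mat) != length(cell_ids)) {
    stop("structural mismatch in reduction '", name, "': ", nrow(mat),
         " rows but ", length(cell_ids), " cells", call. = FALSE)
  }
  if (!is.null(rownames(mat))) {
    if (!setequal(rownames(mat), cell_ids)) {
      stop("reduction '", name, "' does not cover exactly the object's cells",
           call. = FALSE)
    }
    mat <- mat[cell_ids, , drop = FALSE]
  } else {
    rownames(mat) <- cell_ids
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("dim", seq_len(ncol(mat)))
  }
  mat
}

#' @export
print.pi_obj <- function(x, ...) {
  cat("Post-integration (Pi) object\n")
  cat("  ", nrow(x$expression), " genes x ", nrow(x$cells), " cells; ",
      length(unique(x$cells$cluster)), " clusters, ",
      length(unique(x$cells$sample_id)), " samples, ",
      length(unique(x$cells$group)), " groups\n", sep = "")
  cat("  reductions: ",
      if (length(x$reductions)) paste(names(x$reductions), collapse = ", ")
      else "<none>", "\n", sep = "")
  cat("  neighbor graphs: ",
      if (length(x$neighbor_graphs)) paste(names(x$neighbor_graphs),
                                           collapse = ", ")
      else "<none>", "\n", sep = "")
  filled <- c(exp_freq = !is.null(x$exp_freq), markers = !is.null(x$markers),
              ds = !is.null(x$ds), cell_prop = length(x$cell_prop) > 0)
  cat("  analysis slots filled: ",
      if (any(filled)) paste(names(filled)[filled], collapse = ", ")
      else "<none>", "\n", sep = "")
  cat("  children: ",
      if (length(x$children)) paste(names(x$children), collapse = ", ")
      else "<none>",
      if (!is.null(x$parent)) "  (has parent)" else "", "\n", sep = "")
  invisible(x)
}

#' Number of cells in a Pi object
#' @param pi A `pi_obj`.
#' @return Integer cell count.
#' @export
n_cells <- function(pi) nrow(pi$cells)

#' Validate the internal consistency of a Pi object
#'
#' Checks the structural invariants: expression/metadata dimension agreement,
#' unique non-missing metadata, reductions and neighbor graphs covering
#' exactly the object's cells in canonical order, and child links whose cell
#' sets are subsets of this object's cells. Called by the readers and useful
#' after manual surgery.
#'
#' @param pi A `pi_obj`.
#' @return `pi`, invisibly; errors describe the first violated invariant.
#' @export
validate_pi <- function(pi) {
  stopifnot(inherits(pi, "pi_obj"))
  ids <- pi$cells$cell_id
  if (ncol(pi$expression) != length(ids)) {
    stop("expression column count does not match the number of cells",
         call. = FALSE)
  }
  if (!identical(colnames(pi$expression), ids)) {
    stop("expression columns are not in canonical cell order", call. = FALSE)
  }
  for (nm in names(pi$reductions)) {
    if (!identical(rownames(pi$reductions[[nm]]), ids)) {
      stop("reduction '", nm, "' does not match the canonical cell order",
           call. = FALSE)
    }
  }
  for (nm in names(pi$neighbor_graphs)) {
    g <- pi$neighbor_graphs[[nm]]
    if (!identical(g$cell_ids, ids)) {
      stop("neighbor graph '", nm, "' does not match the canonical cell order",
           call. = FALSE)
    }
  }
  for (nm in names(pi$children)) {
    link <- pi$children[[nm]]
    unknown <- setdiff(link$cell_ids, ids)
    if (length(unknown)) {
      stop("child '", nm, "' references unknown cell(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    if (!setequal(names(link$label_map), link$cell_ids)) {
      stop("child '", nm, "' label_map does not cover exactly its cells",
           call. = FALSE)
    }
    validate_pi(link$child)
  }
  invisible(pi)
}
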