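#' Attach a subclustering object as a named child
#'
#' Links a child Pi object (a re-clustered subset of this object's cells,
#' e.g. the T-cell compartment of a PBMC object) into its parent. The link
#' records the member cell ids, the child object itself, and a per-cell map
#' from parent cell id to the child's cluster label. Children may themselves
#' carry children, giving arbitrarily deep hierarchies.
#'
#' The child's own analysis slots are never touched; only its parent
#' back-reference is set inside the stored copy.
#'
#' @param parent A `pi_obj`.
#' @param name Unique child name (e.g. `"Tcells"`).
#' @param cell_ids Parent cell ids included in the child. Must equal the
#'   child's cell set (order may differ; all cross-object operations key by
#'   cell id, the parent's order stays canonical).
#' @param child A `pi_obj` over exactly `cell_ids`.
#' @return The parent with one more entry in `$children`.
#' @export
attach_subcluster <- function(parent, name, cell_ids, child) {
  stopifnot(inherits(parent, "pi_obj"), inherits(child, "pi_obj"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a single non-empty string", call. = FALSE)
  }
  if (name %in% names(parent$children)) {
    stop("a child named '", name, "' is already attached", call. = FALSE)
  }
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) {
    stop("`cell_ids` contains duplicates", call. = FALSE)
  }
  unknown <- setdiff(cell_ids, parent$cells$cell_id)
  if (length(unknown)) {
    stop("cell id(s) not present in the parent: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) ", ...", call. = FALSE)
  }
  if (!setequal(child$cells$cell_id, cell_ids)) {
    stop("the child's cells must be exactly `cell_ids`", call. = FALSE)
  }

  child$parent <- list(
    name = name,
    # identity map: child cells keep their parent cell ids
    cell_map = stats::setNames(child$cells$cell_id, child$cells$cell_id)
  )
  label_map <- stats::setNames(
    child$cells$cluster[match(cell_ids, child$cells$cell_id)], cell_ids)

  parent$children[[name]] <- list(
    name = name,
    cell_ids = cell_ids,
    child = child,
    label_map = label_map
  )
  parent
}

#' Resolve per-cell cluster labels across the subcluster hierarchy
#'
#' Walks the parent/child tree and assigns every cell of `root` the deepest
#' available cluster label at or above the requested level. Cells that were
#' never subclustered keep their root-level label, so a single labeling mixes
#' main-cluster and subcluster granularity -- the labeling used for
#' re-projection summaries, marker tables and proportion analysis.
#'
#' @param root A `pi_obj`.
#' @param level `"leaf"` (default, descend as deep as links go) or a
#'   non-negative integer depth; `0` returns the root's own cluster column.
#' @param priority Optional character vector of child names. When children
#'   overlap, labels are taken from the first listed child that covers a
#'   cell; without a priority, any overlap raises an ambiguity error listing
#'   the conflicted cell ids.
#' @return A data.frame with columns `cell_id` and `label`, in the root's
#'   canonical cell order.
#' @export
resolve_labels <- function(root, level = "leaf", priority = NULL) {
  stopifnot(inherits(root, "pi_obj"))
  if (identical(level, "leaf")) {
    depth <- Inf
  } else {
    if (!is.numeric(level) || length(level) != 1L || level < 0 ||
        (is.finite(level) && level != floor(level))) {
      stop("`level` must be \"leaf\" or a non-negative integer", call. = FALSE)
    }
    depth <- level
  }

  ids <- root$cells$cell_id
  labels <- stats::setNames(root$cells$cluster, ids)

  if (depth >= 1 && length(root$children)) {
    kids <- root$children
    if (!is.null(priority)) {
      bad <- setdiff(priority, names(kids))
      if (length(bad)) {
        stop("unknown child name(s) in `priority`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      kids <- kids[c(priority, setdiff(names(kids), priority))]
    }
    assigned <- character(0)
    for (nm in names(kids)) {
      link <- kids[[nm]]
      member <- link$cell_ids
      overlap <- intersect(member, assigned)
      if (length(overlap)) {
        if (is.null(priority)) {
          stop("ambiguous labels: cell(s) covered by more than one child (",
               paste(utils::head(overlap, 5), collapse = ", "),
               if (length(overlap) > 5) ", ...",
               "); pass `priority` to arbitrate", call. = FALSE)
        }
        member <- setdiff(member, assigned)
      }
      sub <- resolve_labels(link$child,
                            if (is.infinite(depth)) "leaf" else depth - 1)
      sub_labels <- stats::setNames(sub$label, sub$cell_id)
      labels[member] <- sub_labels[member]
      assigned <- c(assigned, member)
    }
  }

  data.frame(cell_id = ids, label = unname(labels[ids]),
             stringsAsFactors = FALSE)
}

#' Names and cell sets of all descendants of a Pi object
#'
#' @param pi A `pi_obj`.
#' @return Named list mapping each descendant child name (at any depth) to
#'   the ids of the cells it covers, expressed in `pi`'s cell id universe.
#' @export
child_cell_sets <- function(pi) {
  out <- list()
  for (nm in names(pi$children)) {
    link <- pi$children[[nm]]
    out[[nm]] <- link$cell_ids
    deeper <- child_cell_sets(link$child)
    for (dn in names(deeper)) {
      if (dn %in% names(out)) {
        stop("duplicate child name '", dn, "' across hierarchy levels",
             call. = FALSE)
      }
      out[[dn]] <- deeper[[dn]]
    }
  }
  out
}
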