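#' Configuration for subcluster re-projection
#'
#' @param k Neighbors per cell for all KNN graphs (parent and children).
#' @param w Weight in `[0, 1]` controlling how much of the parent's global
#'   structure is preserved: for each subclustered cell, up to
#'   `k1 = round(w * k)` of its nearest parent-level neighbors *from a
#'   different main cluster* are retained and merged with the `k - k1`
#'   nearest neighbors from its subcluster graph. `w = 1` (default) keeps
#'   all available cross-cluster edges, balancing local subcluster
#'   separability against global connectivity; smaller `w` separates
#'   subclusters more aggressively, `w = 0` uses the subcluster graph alone.
#' @param scaling Distance-scaling statistic for child graphs; only
#'   `"mean-distance"` is implemented (see [rescale_child_distances()]).
#' @param seed Integer seed for the embedding layout. Graph construction is
#'   deterministic and unaffected.
#' @param embed_params Named list passed through to the layout backend
#'   ([uwot::umap()]), e.g. `min_dist`.
#' @return A `reprojection_config` list.
#' @export
reprojection_config <- function(k = 20, w = 1, scaling = "mean-distance",
                                seed = 42, embed_params = list()) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  scaling <- match.arg(scaling)
  structure(list(k = k, w = w, scaling = scaling, seed = as.integer(seed),
                 embed_params = embed_params),
            class = "reprojection_config")
}

# round-half-away-from-zero; w and k are nonnegative here
round_half_up <- function(x) floor(x + 0.5)

#' Rescale a subcluster KNN graph to the parent's distance scale
#'
#' Child graphs are built on the child's own reduction, whose distance units
#' are arbitrary relative to the parent's. Before merging, every child
#' distance is multiplied by `s = A_p / A_c`, where `A_c` is the mean of all
#' neighbor distances in the child graph and `A_p` is the mean of parent
#' neighbor distances over edges whose both endpoints lie inside the linked
#' cell set -- so the average within-subcluster distance aligns with the
#' parent's. Neighbor ranks are unchanged.
#'
#' If the parent graph has no edge fully internal to the subset, the mean
#' over parent edges with at least one endpoint in the set is used instead;
#' if there is none of those either, `s = 1` with a warning.
#'
#' @param parent_graph `neighbor_graph` over the parent's cells.
#' @param child_graph `neighbor_graph` over the child's cells.
#' @param link The `SubclusterLink` entry (from `parent$children`) mapping
#'   the child into the parent.
#' @return The child graph with rescaled distances; the factor is stored in
#'   `attr(, "scale_factor")`.
#' @export
rescale_child_distances <- function(parent_graph, child_graph, link) {
  a_c <- mean(child_graph$dist, na.rm = TRUE)
  if (!is.finite(a_c) || a_c == 0) {
    stop("degenerate child graph: all neighbor distances are zero",
         call. = FALSE)
  }
  members <- link$cell_ids
  rows <- match(members, parent_graph$cell_ids)
  if (anyNA(rows)) {
    stop("link cells missing from the parent graph", call. = FALSE)
  }
  sub_idx <- parent_graph$idx[rows, , drop = FALSE]
  sub_dist <- parent_graph$dist[rows, , drop = FALSE]
  inside <- matrix(parent_graph$cell_ids[sub_idx] %in% members,
                   nrow = nrow(sub_idx))
  if (any(inside)) {
    a_p <- mean(sub_dist[inside])
  } else {
    # >= 1 endpoint in the set: all edges out of member rows, plus edges
    # from non-member rows that point into the set
    other <- setdiff(seq_along(parent_graph$cell_ids), rows)
    into <- matrix(parent_graph$cell_ids[parent_graph$idx[other, ,
                                                          drop = FALSE]]
                   %in% members, nrow = length(other))
    touching <- c(sub_dist, parent_graph$dist[other, , drop = FALSE][into])
    if (length(touching)) {
      a_p <- mean(touching)
    } else {
      warning("no parent edge touches the subcluster; using scale factor 1")
      a_p <- a_c
    }
  }
  s <- a_p / a_c
  child_graph$dist <- child_graph$dist * s
  attr(child_graph, "scale_factor") <- s
  child_graph
}

#' Merge the parent KNN graph with rescaled subcluster graphs
#'
#' The core of the re-projection algorithm. For each parent cell belonging
#' to a subcluster `S` with graph `G_S` (distances already rescaled):
#'
#' 1. from the cell's parent neighbor list, in rank order, up to
#'    `k1 = round(w * k)` neighbors whose parent-level cluster differs from
#'    the cell's own are retained (the cross-cluster edges carrying global
#'    structure); `r <= k1` is the number actually available;
#' 2. the `k - r` nearest neighbors of the cell in `G_S` are added next.
#'    A child candidate that duplicates a step-1 neighbor is not added
#'    again: it is skipped without consuming the quota, and if its rescaled
#'    distance is smaller than the retained parent distance the kept edge
#'    adopts the smaller distance and child provenance;
#' 3. the combined list is sorted ascending by distance (ties: parent edges
#'    first, then neighbor cell order) and truncated to `k`.
#'
#' Cells in no subcluster keep their parent rows verbatim -- indices and
#' distances bit-identical, provenance `"parent"`. Rows end up shorter than
#' `k` only when parent and child lists jointly offer fewer than `k`
#' distinct candidates; such rows are NA-padded and a warning is recorded.
#'
#' @param parent_graph `neighbor_graph` over the parent's cells.
#' @param children Named list; each element a list with components `graph`
#'   (the rescaled child `neighbor_graph`) and `link` (the parent's
#'   `SubclusterLink` for it). Cell sets must be mutually disjoint.
#' @param clusters Character vector of parent-level cluster labels, aligned
#'   with `parent_graph$cell_ids`; defines "different cluster" in step 1.
#' @param config A [reprojection_config()].
#' @return A `merged_graph` over the parent's cells with per-edge provenance.
#' @export
merge_neighbors <- function(parent_graph, children, clusters,
                            config = reprojection_config()) {
  stopifnot(inherits(config, "reprojection_config"))
  n <- length(parent_graph$cell_ids)
  if (length(clusters) != n) {
    stop("`clusters` must align with the parent graph's cells", call. = FALSE)
  }
  k <- parent_graph$k
  k1 <- as.integer(round_half_up(config$w * k))

  membership <- rep(NA_character_, n)
  child_rows <- vector("list", n)   # per parent cell: list(idx, dist) in parent positions
  for (nm in names(children)) {
    ch <- children[[nm]]
    rows <- match(ch$link$cell_ids, parent_graph$cell_ids)
    if (anyNA(rows)) {
      stop("child '", nm, "' references cells absent from the parent graph",
           call. = FALSE)
    }
    if (any(!is.na(membership[rows]))) {
      stop("subcluster cell sets overlap; re-projection requires disjoint ",
           "children", call. = FALSE)
    }
    membership[rows] <- nm
    g <- ch$graph
    to_parent <- match(g$cell_ids, parent_graph$cell_ids)
    child_of_parent <- match(ch$link$cell_ids, g$cell_ids)
    for (j in seq_along(rows)) {
      row <- graph_row(g, child_of_parent[j])
      child_rows[[rows[j]]] <- list(idx = to_parent[row$idx], dist = row$dist)
    }
  }

  idx <- matrix(NA_integer_, n, k)
  dd <- matrix(NA_real_, n, k)
  pv <- matrix(NA_character_, n, k)
  short_cells <- character(0)

  for (i in seq_len(n)) {
    nm <- membership[i]
    if (is.na(nm)) {
      idx[i, ] <- parent_graph$idx[i, ]
      dd[i, ] <- parent_graph$dist[i, ]
      pv[i, ] <- "parent"
      next
    }
    tag <- paste0("child:", nm)
    p_idx <- parent_graph$idx[i, ]
    p_dist <- parent_graph$dist[i, ]
    cross <- which(clusters[p_idx] != clusters[i])
    sel <- cross[seq_len(min(k1, length(cross)))]
    ids <- p_idx[sel]
    ds <- p_dist[sel]
    prov <- rep("parent", length(sel))
    r <- length(sel)

    crow <- child_rows[[i]]
    quota <- k - r
    taken <- 0L
    j <- 1L
    while (taken < quota && j <= length(crow$idx)) {
      cand <- crow$idx[j]
      pos <- match(cand, ids)
      if (!is.na(pos)) {
        if (crow$dist[j] < ds[pos]) {
          ds[pos] <- crow$dist[j]
          prov[pos] <- tag
        }
      } else {
        ids <- c(ids, cand)
        ds <- c(ds, crow$dist[j])
        prov <- c(prov, tag)
        taken <- taken + 1L
      }
      j <- j + 1L
    }

    o <- order(ds, prov != "parent", ids)
    m <- min(k, length(o))
    o <- o[seq_len(m)]
    idx[i, seq_len(m)] <- ids[o]
    dd[i, seq_len(m)] <- ds[o]
    pv[i, seq_len(m)] <- prov[o]
    if (m < k) short_cells <- c(short_cells, parent_graph$cell_ids[i])
  }

  if (length(short_cells)) {
    warning("merged rows shorter than k for ", length(short_cells),
            " cell(s): ", paste(utils::head(short_cells, 5), collapse = ", "),
            call. = FALSE)
  }
  new_neighbor_graph(parent_graph$cell_ids, k, idx, dd, provenance = pv)
}

#' Two-dimensional layout of a merged neighbor graph
#'
#' Computes a UMAP layout that consumes the merged neighbor lists as the
#' precomputed neighbor structure -- neighbors are never recomputed from
#' coordinates, so the layout reflects exactly the merged graph. Each cell
#' is prepended as its own zero-distance first neighbor, as the backend
#' expects; NA-padded short rows are completed by repeating their last
#' available neighbor (a duplicate edge is absorbed by the backend's fuzzy
#' union). The layout is deterministic given `config$seed`.
#'
#' @param merged A `neighbor_graph` or `merged_graph`.
#' @param config A [reprojection_config()]; `seed` and `embed_params` are
#'   used here.
#' @return Numeric matrix (cells x 2) with the graph's cell ids as row
#'   names; all coordinates finite.
#' @export
embed_merged <- function(merged, config = reprojection_config()) {
  stopifnot(inherits(merged, "neighbor_graph"),
            inherits(config, "reprojection_config"))
  n <- length(merged$cell_ids)
  lens <- rowSums(!is.na(merged$idx))
  if (any(lens == 0L)) {
    stop("cells with empty neighbor lists cannot be embedded: ",
         paste(utils::head(merged$cell_ids[lens == 0L], 5), collapse = ", "),
         call. = FALSE)
  }
  k <- merged$k
  idx <- cbind(seq_len(n), merged$idx)
  dd <- cbind(rep(0, n), merged$dist)
  for (i in which(lens < k)) {     # pad short rows with their last neighbor
    last <- lens[i] + 1L
    fill <- (last + 1L):(k + 1L)
    idx[i, fill] <- idx[i, last]
    dd[i, fill] <- dd[i, last]
  }
  args <- c(list(X = NULL, nn_method = list(idx = idx, dist = dd),
                 n_components = 2, n_threads = 1, n_sgd_threads = 0,
                 verbose = FALSE),
            config$embed_params)
  set.seed(config$seed)
  emb <- do.call(uwot::umap, args)
  if (!all(is.finite(emb))) {
    stop("embedding produced non-finite coordinates", call. = FALSE)
  }
  rownames(emb) <- merged$cell_ids
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Re-project subcluster structure onto the parent embedding
#'
#' Orchestrates the full algorithm: build the exact KNN graph of the root
#' and of each requested child, rescale child distances to the parent's
#' scale, merge the neighbor lists under the `w`-weighted retention rule,
#' and compute a fresh 2-D layout from the merged graph. The merged graph is
#' stored under `neighbor_graphs[["reprojected"]]` and the layout under
#' `reductions[["reprojected.umap"]]`.
#'
#' The procedure is recursive: a child that itself has children is first
#' re-projected, and its merged graph (not its plain KNN graph) is used as
#' that child's graph -- so multi-level hierarchies integrate bottom-up.
#' With no children requested the layout is that of the parent graph alone.
#'
#' @param root A `pi_obj`.
#' @param children Character vector of child names to integrate; defaults to
#'   all attached children.
#' @param config A [reprojection_config()].
#' @param reduction Reduction name used for the root's KNN graph (default:
#'   its first reduction). Each child uses its own same-named reduction if
#'   present, otherwise its first one.
#' @return `root` with the merged graph and the new layout stored; the
#'   updated (re-projected) children are stored back into their links.
#' @export
reproject <- function(root, children = names(root$children),
                      config = reprojection_config(), reduction = NULL) {
  stopifnot(inherits(root, "pi_obj"))
  unknown <- setdiff(children, names(root$children))
  if (length(unknown)) {
    stop("[stage build_knn] unknown child name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(reduction)) reduction <- names(root$reductions)[1]

  parent_graph <- with_stage("build_knn",
    build_knn(root, reduction, k = config$k))

  scaled <- list()
  for (nm in children) {
    link <- root$children[[nm]]
    ch <- link$child
    if (length(ch$children)) {
      ch <- reproject(ch, names(ch$children), config,
                      reduction = if (reduction %in% names(ch$reductions))
                        reduction)
      g <- ch$neighbor_graphs[["reprojected"]]
      root$children[[nm]]$child <- ch
      link <- root$children[[nm]]
    } else {
      child_red <- if (!is.null(reduction) &&
                       reduction %in% names(ch$reductions)) reduction
      g <- with_stage("build_knn", build_knn(ch, child_red, k = config$k))
    }
    g <- with_stage("rescale_child_distances",
                    rescale_child_distances(parent_graph, g, link))
    scaled[[nm]] <- list(graph = g, link = link)
  }

  merged <- if (length(scaled)) {
    with_stage("merge_neighbors",
               merge_neighbors(parent_graph, scaled,
                               clusters = root$cells$cluster, config))
  } else {
    new_neighbor_graph(parent_graph$cell_ids, parent_graph$k,
                       parent_graph$idx, parent_graph$dist,
                       provenance = matrix("parent",
                                           nrow(parent_graph$idx),
                                           parent_graph$k))
  }
  emb <- with_stage("embed_merged", embed_merged(merged, config))

  root$neighbor_graphs[["reprojected"]] <- merged
  root$reductions[["reprojected.umap"]] <- emb
  root
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}
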