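# Programmatic fixtures shared across test files.

# minimal Pi object from coordinates + labels (expression = sparse zeros
# unless given)
tiny_pi <- function(coords, clusters, sample_id = "s1", group = "A",
                    expr = NULL, ids = NULL) {
  n <- nrow(coords)
  if (is.null(ids)) ids <- sprintf("c%03d", seq_len(n))
  if (is.null(expr)) {
    expr <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(1L, n),
                                 dimnames = list("g1", ids))
  }
  rownames(coords) <- ids
  create_pi(expr,
            data.frame(cell_id = ids,
                       sample_id = rep_len(sample_id, n),
                       group = rep_len(group, n),
                       cluster = clusters,
                       stringsAsFactors = FALSE),
            reductions = list(pca = coords))
}

# randomized merge instance: clustered parent in 2-D, 1-2 subclustered
# main clusters with fresh child coordinates, everything <= 100 cells
random_merge_instance <- function(seed) {
  set.seed(seed)
  n <- sample(40:100, 1)
  n_clust <- sample(2:3, 1)
  cl <- rep_len(seq_len(n_clust), n)
  centers <- matrix(stats::rnorm(n_clust * 2, sd = 8), n_clust, 2)
  coords <- centers[cl, ] + matrix(stats::rnorm(n * 2), n, 2)
  parent <- tiny_pi(coords, paste0("C", cl))
  k <- sample(3:8, 1)
  parent_graph <- build_knn(parent, "pca", k = k)

  n_children <- sample(1:min(2, n_clust), 1)
  target_clusters <- sample(seq_len(n_clust), n_children)
  children <- list()
  for (ci in seq_len(n_children)) {
    nm <- paste0("sub", ci)
    member_pos <- which(cl == target_clusters[ci])
    ids <- parent$cells$cell_id[member_pos]
    ccoords <- matrix(stats::rnorm(length(ids) * 2, sd = stats::runif(1, 0.5, 4)),
                      length(ids), 2)
    child <- tiny_pi(ccoords, rep_len(c("a", "b"), length(ids)), ids = ids)
    parent <- attach_subcluster(parent, nm, ids, child)
    g <- build_knn(child, "pca", k = k)
    g <- rescale_child_distances(parent_graph, g, parent$children[[nm]])
    children[[nm]] <- list(graph = g, link = parent$children[[nm]])
  }
  list(parent = parent, parent_graph = parent_graph, children = children,
       clusters = parent$cells$cluster, k = k)
}

# 12-cell two-level hierarchy with hand-checkable labels:
# root: T (t1..t6), B (b1..b6); child over T: CD4 (t1..t4) / CD8 (t5,t6);
# grandchild over CD4 cells: CD4mem (t1,t2) / CD4naive (t3,t4)
toy_hierarchy <- function() {
  ids <- c(paste0("t", 1:6), paste0("b", 1:6))
  coords <- cbind(c(1:6, 101:106), 0)
  root <- tiny_pi(coords, rep(c("T", "B"), each = 6), ids = ids)
  t_ids <- paste0("t", 1:6)
  child <- tiny_pi(cbind(1:6, 0), rep(c("CD4", "CD8"), c(4, 2)),
                   ids = t_ids)
  cd4_ids <- paste0("t", 1:4)
  grandchild <- tiny_pi(cbind(1:4, 0),
                        rep(c("CD4mem", "CD4naive"), each = 2),
                        ids = cd4_ids)
  child <- attach_subcluster(child, "CD4sub", cd4_ids, grandchild)
  root <- attach_subcluster(root, "Tsub", t_ids, child)
  root
}
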