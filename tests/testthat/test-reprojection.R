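ng <- screproject:::new_neighbor_graph

test_that("rescaling aligns child distances to the parent scale", {
  # parent: 6 cells, members p1..p3 whose internal edges all have length 2
  p_idx <- matrix(c(2L, 3L, 1L, 5L, 6L, 4L), ncol = 1)
  p_dist <- matrix(c(2, 2, 2, 7, 7, 7), ncol = 1)
  parent <- ng(paste0("p", 1:6), 1L, p_idx, p_dist)
  child <- ng(paste0("p", 1:3), 1L, matrix(c(2L, 3L, 1L), ncol = 1),
              matrix(c(1, 1, 1), ncol = 1))
  link <- list(cell_ids = paste0("p", 1:3))
  scaled <- rescale_child_distances(parent, child, link)
  expect_equal(attr(scaled, "scale_factor"), 2)
  expect_equal(scaled$dist, matrix(c(2, 2, 2), ncol = 1))
  # ranks are untouched
  expect_identical(scaled$idx, child$idx)
})

test_that("the scale factor is invariant to uniform child rescaling", {
  set.seed(5)
  inst <- random_merge_instance(5)
  link <- inst$children[[1]]$link
  child_pi <- link$child
  g1 <- build_knn(child_pi, "pca", k = inst$k)
  child_pi$reductions$pca <- child_pi$reductions$pca * 17.3
  g2 <- build_knn(child_pi, "pca", k = inst$k)
  r1 <- rescale_child_distances(inst$parent_graph, g1, link)
  r2 <- rescale_child_distances(inst$parent_graph, g2, link)
  expect_equal(r1$dist, r2$dist, tolerance = 1e-10)
})

test_that("a planted coordinate-scale mismatch is recovered", {
  set.seed(60)
  members <- matrix(rnorm(60), 30, 2)
  others <- matrix(rnorm(60), 30, 2) + 20
  parent <- tiny_pi(rbind(members, others),
                    rep(c("in", "out"), each = 30))
  ids <- parent$cells$cell_id[1:30]
  child_pi <- tiny_pi(members / 3.5, rep_len(c("a", "b"), 30), ids = ids)
  parent <- attach_subcluster(parent, "sub", ids, child_pi)
  pg <- build_knn(parent, "pca", k = 5)
  cg <- build_knn(child_pi, "pca", k = 5)
  s <- attr(rescale_child_distances(pg, cg, parent$children$sub),
            "scale_factor")
  expect_gt(s, 3.5 * 0.9)
  expect_lt(s, 3.5 * 1.1)
})

test_that("w = 0 reduces subclustered rows to the rescaled child graph", {
  inst <- random_merge_instance(21)
  merged <- merge_neighbors(inst$parent_graph, inst$children, inst$clusters,
                            reprojection_config(k = inst$k, w = 0))
  for (nm in names(inst$children)) {
    ch <- inst$children[[nm]]
    to_parent <- match(ch$graph$cell_ids, inst$parent_graph$cell_ids)
    for (cid in ch$link$cell_ids) {
      i <- match(cid, inst$parent_graph$cell_ids)
      ci <- match(cid, ch$graph$cell_ids)
      expect_identical(merged$idx[i, ],
                       to_parent[ch$graph$idx[ci, ]])
      expect_equal(merged$dist[i, ], ch$graph$dist[ci, ])
      expect_true(all(merged$provenance[i, ] == paste0("child:", nm)))
    }
  }
})

test_that("cells outside any subcluster keep their parent rows verbatim", {
  for (seed in c(2, 9)) {
    inst <- random_merge_instance(seed)
    merged <- merge_neighbors(inst$parent_graph, inst$children,
                              inst$clusters,
                              reprojection_config(k = inst$k, w = 1))
    member <- inst$parent_graph$cell_ids %in%
      unlist(lapply(inst$children, function(ch) ch$link$cell_ids))
    expect_identical(merged$idx[!member, , drop = FALSE],
                     inst$parent_graph$idx[!member, , drop = FALSE])
    expect_identical(merged$dist[!member, , drop = FALSE],
                     inst$parent_graph$dist[!member, , drop = FALSE])
    expect_true(all(merged$provenance[!member, ] == "parent"))
  }
})

test_that("merged rows are sorted, complete and provenance-consistent", {
  inst <- random_merge_instance(33)
  merged <- merge_neighbors(inst$parent_graph, inst$children, inst$clusters,
                            reprojection_config(k = inst$k, w = 0.5))
  expect_true(all(apply(merged$dist, 1,
                        function(r) !is.unsorted(r[!is.na(r)]))))
  expect_true(all(rowSums(!is.na(merged$idx)) == inst$k))
  # provenance audit: every edge exists in the object that is tagged
  for (i in seq_along(merged$cell_ids)) {
    for (jj in seq_len(inst$k)) {
      tag <- merged$provenance[i, jj]
      j <- merged$idx[i, jj]
      d <- merged$dist[i, jj]
      if (tag == "parent") {
        hit <- which(inst$parent_graph$idx[i, ] == j)
        expect_true(length(hit) == 1 &&
                      inst$parent_graph$dist[i, hit] == d)
      } else {
        nm <- sub("^child:", "", tag)
        g <- inst$children[[nm]]$graph
        ci <- match(merged$cell_ids[i], g$cell_ids)
        cj <- match(merged$cell_ids[j], g$cell_ids)
        hit <- which(g$idx[ci, ] == cj)
        expect_true(length(hit) == 1 && g$dist[ci, hit] == d)
      }
    }
  }
})

test_that("retained cross-cluster parent edges are monotone in w", {
  inst <- random_merge_instance(44)
  member <- inst$parent_graph$cell_ids %in%
    unlist(lapply(inst$children, function(ch) ch$link$cell_ids))
  counts <- vapply(c(0, 0.25, 0.5, 1), function(w) {
    m <- merge_neighbors(inst$parent_graph, inst$children, inst$clusters,
                         reprojection_config(k = inst$k, w = w))
    sum(m$provenance[member, ] == "parent", na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 0)
})

test_that("config and merge preconditions are enforced", {
  expect_error(reprojection_config(w = 1.5), "\\[0, 1\\]")
  expect_error(reprojection_config(w = -0.1), "\\[0, 1\\]")
  expect_error(reprojection_config(k = 0), ">= 1")

  inst <- random_merge_instance(3)
  dup <- inst$children[c(1, 1)]
  names(dup) <- c("a", "b")
  expect_error(merge_neighbors(inst$parent_graph, dup, inst$clusters,
                               reprojection_config(k = inst$k)),
               "disjoint")
})

test_that("embedding is deterministic, finite, and rejects empty rows", {
  inst <- random_merge_instance(12)
  merged <- merge_neighbors(inst$parent_graph, inst$children, inst$clusters,
                            reprojection_config(k = inst$k, w = 1))
  cfg <- reprojection_config(k = inst$k, seed = 99)
  e1 <- embed_merged(merged, cfg)
  e2 <- embed_merged(merged, cfg)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  expect_identical(rownames(e1), merged$cell_ids)

  hole <- merged
  hole$idx[3, ] <- NA_integer_
  hole$dist[3, ] <- NA_real_
  expect_error(embed_merged(hole, cfg), merged$cell_ids[3])
})

test_that("reproject stores results and handles the degenerate case", {
  fix <- generate_fixture(fixture_plan(seed = 4, cells_per_sample = 30,
                                       compute_embedding = FALSE))
  cfg <- reprojection_config(k = 10, seed = 2)
  # zero children: layout of the parent graph alone
  none <- reproject(fix$pi, children = character(0), config = cfg)
  pg <- build_knn(fix$pi, "pca", k = 10)
  expect_equal(none$reductions[["reprojected.umap"]],
               embed_merged(pg, cfg))
  expect_true(all(none$neighbor_graphs$reprojected$provenance == "parent"))

  full <- reproject(fix$pi, config = cfg)
  expect_s3_class(full$neighbor_graphs$reprojected, "merged_graph")
  expect_identical(dim(full$reductions[["reprojected.umap"]]),
                   c(nrow(full$cells), 2L))
})

test_that("multi-level hierarchies re-project recursively", {
  root <- toy_hierarchy()
  cfg <- reprojection_config(k = 2, seed = 7)
  out <- reproject(root, "Tsub", cfg)
  expect_true("reprojected.umap" %in% names(out$reductions))
  # the child was itself re-projected and stored back
  child <- out$children$Tsub$child
  expect_true("reprojected" %in% names(child$neighbor_graphs))
  expect_true("reprojected.umap" %in% names(child$reductions))
})
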