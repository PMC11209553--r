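#' Per-gene expression frequency by cluster
#'
#' For every gene and cluster, the fraction of the cluster's cells in which
#' the gene is detected (raw value strictly greater than zero -- no minimum
#' count threshold, so the result is invariant to any monotone positive
#' rescaling of the expression values).
#'
#' @param pi A `pi_obj`.
#' @param level Label level: `"current"` uses the object's own `cluster`
#'   column; `"leaf"` or an integer depth resolves labels through the child
#'   hierarchy (see [resolve_labels()]).
#' @return Numeric genes x clusters matrix with entries in `[0, 1]`.
#' @export
expression_frequency <- function(pi, level = "current") {
  labels <- level_labels(pi, level)
  detected <- pi$expression > 0
  groups <- split(seq_along(labels), labels)
  out <- vapply(groups,
                function(ix) Matrix::rowMeans(detected[, ix, drop = FALSE]),
                numeric(nrow(pi$expression)))
  out <- matrix(out, nrow = nrow(pi$expression),
                dimnames = list(rownames(pi$expression), names(groups)))
  out
}

level_labels <- function(pi, level) {
  if (identical(level, "current")) pi$cells$cluster
  else resolve_labels(pi, level)$label
}

#' One-vs-rest marker detection
#'
#' For each cluster, every gene is tested with a two-sided Wilcoxon rank-sum
#' test of its expression in the cluster's cells against all other cells.
#' The effect is the log2 fold-change of the group means (small pseudocount
#' for stability); p-values are Benjamini-Hochberg adjusted across genes
#' within each cluster, and rows are ranked by adjusted p, then effect.
#'
#' @param pi A `pi_obj`.
#' @param level Label level (see [expression_frequency()]).
#' @param min_cells Clusters smaller than this are skipped with a warning.
#' @return data.frame with columns `cluster`, `gene`, `avg_log2fc`, `p`,
#'   `p_adj`, ordered within cluster by rank.
#' @export
find_markers <- function(pi, level = "current", min_cells = 3L) {
  labels <- level_labels(pi, level)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    stop("marker detection needs at least 2 clusters", call. = FALSE)
  }
  expr <- pi$expression
  eps <- 1e-9
  res <- vector("list", length(clusters))
  names(res) <- clusters
  for (cl in clusters) {
    in_ix <- which(labels == cl)
    if (length(in_ix) < min_cells) {
      warning("cluster '", cl, "' has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    x_in <- as.matrix(expr[, in_ix, drop = FALSE])
    x_out <- as.matrix(expr[, -in_ix, drop = FALSE])
    m_in <- rowMeans(x_in)
    m_out <- rowMeans(x_out)
    lfc <- log2((m_in + eps) / (m_out + eps))
    p <- vapply(seq_len(nrow(expr)), function(g) {
      suppressWarnings(stats::wilcox.test(x_in[g, ], x_out[g, ])$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1
    p_adj <- stats::p.adjust(p, method = "BH")
    tab <- data.frame(cluster = cl, gene = rownames(expr),
                      avg_log2fc = lfc, p = p, p_adj = p_adj,
                      stringsAsFactors = FALSE, row.names = NULL)
    res[[cl]] <- tab[order(tab$p_adj, -tab$avg_log2fc), , drop = FALSE]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pseudobulk aggregation
#'
#' Sums raw counts per gene within every (sample, cluster) cell set,
#' producing a small matrix suitable for sample-level differential testing.
#' Column totals conserve the cell-level totals exactly.
#'
#' @param pi A `pi_obj` whose expression holds raw counts (a warning is
#'   emitted if values are non-integer; sums proceed regardless).
#' @param level Label level (see [expression_frequency()]).
#' @return A `pseudobulk` list: `counts` (genes x columns) and `coldata`
#'   (one row per column: `sample_id`, `cluster`, `group`, `n_cells`).
#' @export
pseudobulk <- function(pi, level = "current") {
  labels <- level_labels(pi, level)
  expr <- pi$expression
  if (length(expr@x) && any(expr@x %% 1 != 0)) {
    warning("expression values are not integer counts; ",
            "pseudobulk sums computed anyway", call. = FALSE)
  }
  key <- interaction(pi$cells$sample_id, labels, drop = TRUE, sep = "|")
  key <- factor(key, levels = unique(key))   # stable column order
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key), x = 1,
                              dims = c(length(key), nlevels(key)))
  counts <- as.matrix(expr %*% ind)
  first <- match(levels(key), key)
  coldata <- data.frame(
    sample_id = pi$cells$sample_id[first],
    cluster = labels[first],
    group = pi$cells$group[first],
    n_cells = as.integer(table(key)[levels(key)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  colnames(counts) <- paste(coldata$sample_id, coldata$cluster, sep = "|")
  rownames(counts) <- rownames(expr)
  structure(list(counts = counts, coldata = coldata), class = "pseudobulk")
}

#' Pseudobulk differential-state test for one cluster
#'
#' Compares the two groups' samples within one cluster on depth-normalized,
#' log-transformed pseudobulk profiles: counts-per-million, log2 with
#' pseudocount 1, then a two-sided Welch t-test per gene on the sample
#' values, Benjamini-Hochberg adjusted across genes. Log fold-change is
#' `mean(groups[1]) - mean(groups[2])` on the log2-CPM scale, so swapping
#' the groups flips every sign. Genes with no variation across samples get
#' `p = 1` (no evidence).
#'
#' @param pb A [pseudobulk()] result.
#' @param cluster Cluster whose columns are tested.
#' @param groups Length-2 character vector of group labels; each must have
#'   at least 2 samples in the cluster (sample-level replication is what
#'   makes the pseudobulk test valid, so fewer is an error).
#' @return data.frame with columns `gene`, `log2fc`, `t`, `p`, `p_adj`,
#'   ordered by `p_adj` then by absolute effect; normalization recorded in
#'   attributes.
#' @export
differential_state <- function(pb, cluster, groups) {
  stopifnot(inherits(pb, "pseudobulk"), length(groups) == 2L)
  sel <- pb$coldata$cluster == cluster
  if (!any(sel)) stop("cluster '", cluster, "' not found", call. = FALSE)
  counts <- pb$counts[, sel, drop = FALSE]
  cd <- pb$coldata[sel, , drop = FALSE]
  g1 <- which(cd$group == groups[1])
  g2 <- which(cd$group == groups[2])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("differential state needs >= 2 samples per group in cluster '",
         cluster, "' (found ", length(g1), " and ", length(g2),
         "); pseudobulk testing requires sample-level replication",
         call. = FALSE)
  }
  depth <- colSums(counts)
  depth[depth == 0] <- 1
  lcpm <- log2(sweep(counts, 2, depth, "/") * 1e6 + 1)
  stat <- numeric(nrow(lcpm))
  p <- numeric(nrow(lcpm))
  for (g in seq_len(nrow(lcpm))) {
    x <- lcpm[g, g1]
    y <- lcpm[g, g2]
    tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) {
      stat[g] <- 0
      p[g] <- 1
    } else {
      stat[g] <- unname(tt$statistic)
      p[g] <- tt$p.value
    }
  }
  out <- data.frame(gene = rownames(lcpm),
                    log2fc = rowMeans(lcpm[, g1, drop = FALSE]) -
                             rowMeans(lcpm[, g2, drop = FALSE]),
                    t = stat, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_adj, -abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normalization") <- "log2(CPM + 1)"
  attr(out, "groups") <- groups
  attr(out, "cluster") <- cluster
  out
}

#' Conditional cell-proportion analysis
#'
#' Counts target-cluster cells relative to a caller-chosen reference
#' population -- the denominator that conditions the biological question
#' (e.g. Treg subsets as a fraction of total Tregs, of total T cells, or of
#' all PBMCs; the conclusions can differ when the compartment itself shifts,
#' as in lymphopenia). `"pooled"` mode pools cells per group; `"unpooled"`
#' computes one proportion per sample, the form suited to multi-sample
#' multi-group designs and required by [test_proportions()].
#'
#' @param root A `pi_obj` (labels are resolved to the leaf level).
#' @param target The populations being counted: either the name of an
#'   attached child (its resolved leaf labels become the target clusters) or
#'   a character vector of resolved leaf labels.
#' @param reference The denominator population: `NULL` for all of `root`'s
#'   cells, the name of a child (that child's cell set), or a character
#'   vector of root-level cluster labels. Target cells must be contained in
#'   it.
#' @param mode `"unpooled"` (default) or `"pooled"`.
#' @return A `proportion_table` data.frame with columns `cluster`,
#'   `sample_id` (unpooled only), `group`, `count`, `ref_count`,
#'   `proportion`; `mode`, `reference` and `target` recorded as attributes.
#'   Samples with zero reference cells are dropped with a warning.
#' @export
cell_proportions <- function(root, target, reference = NULL,
                             mode = c("unpooled", "pooled")) {
  stopifnot(inherits(root, "pi_obj"))
  mode <- match.arg(mode)
  cells <- root$cells
  leaf <- resolve_labels(root, "leaf")$label
  kids <- child_cell_sets(root)

  ref_name <- "all"
  if (is.null(reference) || identical(reference, "all")) {
    ref_ids <- cells$cell_id
  } else if (length(reference) == 1L && reference %in% names(kids)) {
    ref_ids <- kids[[reference]]
    ref_name <- reference
  } else if (all(reference %in% cells$cluster)) {
    ref_ids <- cells$cell_id[cells$cluster %in% reference]
    ref_name <- paste(reference, collapse = "+")
  } else {
    stop("`reference` must be NULL, a child name, or root cluster label(s)",
         call. = FALSE)
  }

  lab <- leaf
  if (length(target) == 1L && target %in% names(kids)) {
    t_ids <- kids[[target]]
  } else if (all(target %in% leaf)) {
    t_ids <- cells$cell_id[leaf %in% target]
  } else if (all(target %in% cells$cluster)) {
    # root-level populations (e.g. a whole compartment vs all cells)
    t_ids <- cells$cell_id[cells$cluster %in% target]
    lab <- cells$cluster
  } else {
    stop("`target` must be a child name, resolved leaf label(s), or root ",
         "cluster label(s)", call. = FALSE)
  }
  outside <- setdiff(t_ids, ref_ids)
  if (length(outside)) {
    stop("target population is not contained in the reference '", ref_name,
         "' (", length(outside), " cell(s) outside)", call. = FALSE)
  }

  in_ref <- cells$cell_id %in% ref_ids
  in_tgt <- cells$cell_id %in% t_ids
  t_clusters <- sort(unique(lab[in_tgt]))
  sample_group <- unique(cells[c("sample_id", "group")])

  if (mode == "unpooled") {
    ref_n <- table(factor(cells$sample_id[in_ref],
                          levels = sample_group$sample_id))
    empty <- sample_group$sample_id[ref_n == 0]
    if (length(empty)) {
      warning("sample(s) with zero reference cells dropped: ",
              paste(empty, collapse = ", "), call. = FALSE)
      sample_group <- sample_group[!sample_group$sample_id %in% empty, ,
                                   drop = FALSE]
    }
    rows <- expand.grid(cluster = t_clusters,
                        sample_id = sample_group$sample_id,
                        stringsAsFactors = FALSE)
    rows$group <- sample_group$group[match(rows$sample_id,
                                           sample_group$sample_id)]
    cnt <- table(factor(lab[in_tgt], levels = t_clusters),
                 factor(cells$sample_id[in_tgt],
                        levels = sample_group$sample_id))
    rows$count <- as.integer(cnt[cbind(rows$cluster, rows$sample_id)])
    rows$ref_count <- as.integer(ref_n[rows$sample_id])
  } else {
    groups <- unique(cells$group)
    ref_n <- table(factor(cells$group[in_ref], levels = groups))
    rows <- expand.grid(cluster = t_clusters, group = groups,
                        stringsAsFactors = FALSE)
    cnt <- table(factor(lab[in_tgt], levels = t_clusters),
                 factor(cells$group[in_tgt], levels = groups))
    rows$count <- as.integer(cnt[cbind(rows$cluster, rows$group)])
    rows$ref_count <- as.integer(ref_n[rows$group])
  }
  rows$proportion <- rows$count / rows$ref_count
  rows <- rows[order(rows$cluster), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "out.attrs") <- NULL
  structure(rows, class = c("proportion_table", "data.frame"),
            mode = mode, reference = ref_name,
            target = paste(t_clusters, collapse = "+"))
}

#' Two-group test of per-sample proportions
#'
#' For each cluster of an unpooled proportion table, the per-sample
#' proportions of the two groups are compared with a two-sided Wilcoxon
#' rank-sum test; p-values are Benjamini-Hochberg adjusted across the
#' table's clusters. Pooled tables are refused: group testing needs
#' per-sample replication.
#'
#' @param tab An unpooled [cell_proportions()] table.
#' @param groups Length-2 character vector; defaults to the two groups found
#'   in the table (error if not exactly two).
#' @return `tab` with the per-cluster test results (`cluster`, `statistic`,
#'   `p`, `p_adj`) attached as `attr(, "test")`.
#' @export
test_proportions <- function(tab, groups = NULL) {
  stopifnot(inherits(tab, "proportion_table"))
  if (identical(attr(tab, "mode"), "pooled")) {
    stop("pooled tables cannot be tested; use mode = \"unpooled\" ",
         "(testing requires per-sample replication)", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- sort(unique(tab$group))
    if (length(groups) != 2L) {
      stop("table must contain exactly two groups (found ",
           length(groups), ")", call. = FALSE)
    }
  }
  clusters <- unique(tab$cluster)
  stat <- p <- numeric(length(clusters))
  for (i in seq_along(clusters)) {
    sub <- tab[tab$cluster == clusters[i], , drop = FALSE]
    x <- sub$proportion[sub$group == groups[1]]
    y <- sub$proportion[sub$group == groups[2]]
    if (length(x) < 2L || length(y) < 2L) {
      stop("cluster '", clusters[i], "' has fewer than 2 samples in a group",
           call. = FALSE)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    stat[i] <- unname(wt$statistic)
    # fully tied data (e.g. identical proportion vectors): no evidence
    p[i] <- if (is.na(wt$p.value)) 1 else wt$p.value
  }
  res <- data.frame(cluster = clusters, statistic = stat, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "test") <- res
  attr(tab, "groups") <- groups
  tab
}

#' Populate the analysis slots of a Pi object
#'
#' Convenience wrapper computing expression frequency and markers at the
#' requested level and storing them in the object's slots. Proportion and
#' differential-state results are stored by their own calls since they
#' depend on the choice of reference and groups.
#'
#' @param pi A `pi_obj`.
#' @param level Label level (see [expression_frequency()]).
#' @return `pi` with `exp_freq` and `markers` filled.
#' @export
run_quantification <- function(pi, level = "current") {
  pi$exp_freq <- expression_frequency(pi, level)
  pi$markers <- find_markers(pi, level)
  pi
}
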