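# Independent straight-line oracles, deliberately written in a different
# style from the package internals (data-frame bookkeeping, no shared code
# beyond the public data structures).

# exhaustive KNN: all pairwise distances, ties by cell order
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  idx <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    tab <- data.frame(j = seq_len(n), d = d)
    tab <- tab[tab$j != i, ]
    tab <- tab[order(tab$d, tab$j), ]
    idx[i, ] <- tab$j[seq_len(k)]
    dd[i, ] <- tab$d[seq_len(k)]
  }
  list(idx = idx, dist = dd)
}

# brute-force merge of parent + scaled child rows under the w-weighted rule:
# (1) keep up to k1 = round(w*k) cross-cluster parent neighbors in rank
# order; (2) scan the child's row in rank order, filling k - r slots,
# skipping already-kept neighbors (adopting the smaller distance/provenance
# on such a duplicate) and stopping once the quota is filled; (3) sort by
# (distance, parent-first, neighbor order) and truncate to k.
oracle_merge <- function(parent_graph, children, clusters, w) {
  k <- parent_graph$k
  k1 <- floor(w * k + 0.5)
  n <- length(parent_graph$cell_ids)

  member_of <- rep(NA_character_, n)
  child_row_of <- vector("list", n)
  for (nm in names(children)) {
    link <- children[[nm]]$link
    g <- children[[nm]]$graph
    for (cid in link$cell_ids) {
      p_pos <- which(parent_graph$cell_ids == cid)
      member_of[p_pos] <- nm
      c_pos <- which(g$cell_ids == cid)
      keep <- !is.na(g$idx[c_pos, ])
      child_row_of[[p_pos]] <- data.frame(
        idx = match(g$cell_ids[g$idx[c_pos, keep]], parent_graph$cell_ids),
        dist = g$dist[c_pos, keep])
    }
  }

  idx <- matrix(NA_integer_, n, k)
  dd <- matrix(NA_real_, n, k)
  pv <- matrix(NA_character_, n, k)
  for (i in seq_len(n)) {
    nm <- member_of[i]
    if (is.na(nm)) {
      idx[i, ] <- parent_graph$idx[i, ]
      dd[i, ] <- parent_graph$dist[i, ]
      pv[i, ] <- "parent"
      next
    }
    tag <- paste0("child:", nm)
    prow <- data.frame(idx = parent_graph$idx[i, ],
                       dist = parent_graph$dist[i, ], prov = "parent")
    cross <- prow[clusters[prow$idx] != clusters[i], ]
    kept <- utils::head(cross, k1)
    quota <- k - nrow(kept)
    crow <- child_row_of[[i]]
    added <- 0L
    for (j in seq_len(nrow(crow))) {
      if (added >= quota) break
      hit <- which(kept$idx == crow$idx[j])
      if (length(hit)) {
        if (crow$dist[j] < kept$dist[hit]) {
          kept$dist[hit] <- crow$dist[j]
          kept$prov[hit] <- tag
        }
      } else {
        kept <- rbind(kept, data.frame(idx = crow$idx[j],
                                       dist = crow$dist[j], prov = tag))
        added <- added + 1L
      }
    }
    kept <- kept[order(kept$dist, kept$prov != "parent", kept$idx), ]
    kept <- utils::head(kept, k)
    m <- nrow(kept)
    idx[i, seq_len(m)] <- kept$idx
    dd[i, seq_len(m)] <- kept$dist
    pv[i, seq_len(m)] <- kept$prov
  }
  list(idx = idx, dist = dd, provenance = pv)
}

# exhaustive silhouette: s(i) = (b - a) / max(a, b), singletons get 0
brute_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      widths[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (lab in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == lab]))
    }
    widths[i] <- (b - a) / max(a, b)
  }
  widths
}
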