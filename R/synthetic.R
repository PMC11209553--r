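#' Plan for a synthetic hierarchical single-cell fixture
#'
#' Describes a desk-scale dataset with known ground truth that emulates the
#' structure motivating the package: a handful of well-separated main
#' clusters (a PBMC-like mixture of T, B and monocyte blobs), one main
#' cluster containing tight, mutually overlapping subpopulations including a
#' rare one (T helper subsets plus a small Treg-like subset), a multi-sample
#' two-group design with group-dependent composition, and sparse
#' overdispersed counts with planted per-cluster marker genes.
#'
#' Defaults: 8 + 8 samples of 75 cells (1200 cells total), three main
#' clusters, the T cluster split into two overlapping subpopulations plus a
#' 3% rare one, latent separation such that the subpopulations are not
#' resolvable on the parent reduction but are on the child's own reduction.
#'
#' @param seed Integer seed; the whole fixture is a deterministic function
#'   of the plan.
#' @param n_samples Named integer vector: samples per group.
#' @param cells_per_sample Cells drawn per sample.
#' @param main_props Per-group named list of main-cluster proportion
#'   vectors (each summing to 1).
#' @param sub_main Name of the main cluster that is subclustered.
#' @param sub_props Per-group named list of within-`sub_main` subpopulation
#'   proportions (each summing to 1; the smallest entry is the rare
#'   subpopulation and must lie in (0, 0.5]).
#' @param separation_main Distance between main-cluster centers in the
#'   latent space (within-cluster spread is 1).
#' @param separation_sub Distance from the `sub_main` center to each
#'   subpopulation center on the parent reduction; values near 1 make the
#'   subpopulations overlap there.
#' @param separation_child Between-subpopulation center distance on the
#'   child's own reduction, where the subpopulations are resolved.
#' @param child_scale Uniform scale factor applied to the child reduction's
#'   coordinates -- a planted unit mismatch that the distance-rescaling step
#'   must absorb.
#' @param latent_dim Dimensionality of all reductions.
#' @param n_genes,markers_per_cluster,marker_fold Expression model: number
#'   of genes, planted markers per leaf cluster and their fold increase.
#' @param library_size Expected total counts per cell.
#' @param dispersion Gamma-Poisson size parameter (smaller = more
#'   overdispersed).
#' @param k Neighbors used when the fixture computes its baseline embedding.
#' @param ds_effect Optional planted group effect for differential-state
#'   testing: `list(cluster =, group =, fold =, gene = NULL)`; with `gene =
#'   NULL` the strongest-expressed non-marker gene is used.
#' @param compute_embedding Compute a baseline `umap` reduction on the
#'   parent (needed for before/after comparisons).
#' @return A `fixture_plan` list.
#' @export
fixture_plan <- function(seed = 1,
                         n_samples = c(A = 8, B = 8),
                         cells_per_sample = 75,
                         main_props = list(
                           A = c(T = 0.40, B = 0.35, Mono = 0.25),
                           B = c(T = 0.40, B = 0.30, Mono = 0.30)),
                         sub_main = "T",
                         sub_props = list(
                           A = c(Th1 = 0.55, Th2 = 0.42, Treg = 0.03),
                           B = c(Th1 = 0.35, Th2 = 0.62, Treg = 0.03)),
                         separation_main = 9,
                         separation_sub = 1.3,
                         separation_child = 6,
                         child_scale = 2.5,
                         latent_dim = 10,
                         n_genes = 150,
                         markers_per_cluster = 4,
                         marker_fold = 8,
                         library_size = 400,
                         dispersion = 2,
                         k = 20,
                         ds_effect = NULL,
                         compute_embedding = TRUE) {
  groups <- names(n_samples)
  stopifnot(length(groups) == 2L, !is.null(groups))
  for (g in groups) {
    if (abs(sum(main_props[[g]]) - 1) > 1e-8) {
      stop("main_props for group '", g, "' must sum to 1", call. = FALSE)
    }
    if (abs(sum(sub_props[[g]]) - 1) > 1e-8) {
      stop("sub_props for group '", g, "' must sum to 1", call. = FALSE)
    }
    rare <- min(sub_props[[g]])
    if (rare <= 0 || rare > 0.5) {
      stop("rarity fraction must lie in (0, 0.5]", call. = FALSE)
    }
  }
  if (separation_main <= 0 || separation_sub <= 0 || separation_child <= 0) {
    stop("separations must be > 0", call. = FALSE)
  }
  if (!sub_main %in% names(main_props[[1]])) {
    stop("`sub_main` must be one of the main clusters", call. = FALSE)
  }
  # feasibility: the rare subpopulation must yield at least a handful of cells
  expected_rare <- sum(vapply(groups, function(g) {
    n_samples[[g]] * cells_per_sample * main_props[[g]][[sub_main]] *
      min(sub_props[[g]])
  }, numeric(1)))
  if (expected_rare < 5) {
    stop("infeasible plan: expected ", round(expected_rare, 1),
         " rare cells (< 5); increase cells or the rarity fraction",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 cells_per_sample = cells_per_sample,
                 main_props = main_props, sub_main = sub_main,
                 sub_props = sub_props, separation_main = separation_main,
                 separation_sub = separation_sub,
                 separation_child = separation_child,
                 child_scale = child_scale, latent_dim = latent_dim,
                 n_genes = n_genes,
                 markers_per_cluster = markers_per_cluster,
                 marker_fold = marker_fold, library_size = library_size,
                 dispersion = dispersion, k = k, ds_effect = ds_effect,
                 compute_embedding = compute_embedding),
            class = "fixture_plan")
}

#' Generate a synthetic Pi hierarchy with ground truth
#'
#' Realizes a [fixture_plan()]: cells are assigned to samples and leaf
#' populations by multinomial draws from the group's composition vector;
#' latent coordinates place main clusters as well-separated Gaussian blobs
#' and subpopulations as close, overlapping Gaussians inside the
#' subclustered blob; the child object carries its own reduction in which
#' the subpopulations are resolved (and deliberately mis-scaled by
#' `child_scale` to exercise distance rescaling); counts are gamma-Poisson
#' with planted marker shifts. The same seed always yields identical output.
#'
#' @param plan A [fixture_plan()].
#' @return A list with elements `pi` (the parent `pi_obj`, child attached as
#'   `"<sub_main>sub"`, reductions `pca` and -- unless disabled -- a
#'   baseline `umap`) and `truth` (per-cell true labels, planned and
#'   realized compositions, planted markers, the plan).
#' @export
generate_fixture <- function(plan = fixture_plan()) {
  stopifnot(inherits(plan, "fixture_plan"))
  set.seed(plan$seed)
  groups <- names(plan$n_samples)
  mains <- names(plan$main_props[[1]])
  subs <- names(plan$sub_props[[1]])

  # --- cell bookkeeping -----------------------------------------------------
  leaf_levels <- c(subs, setdiff(mains, plan$sub_main))
  leaf_props <- lapply(groups, function(g) {
    mp <- plan$main_props[[g]]
    c(mp[[plan$sub_main]] * plan$sub_props[[g]],
      mp[setdiff(mains, plan$sub_main)])
  })
  names(leaf_props) <- groups

  rows <- list()
  for (g in groups) {
    for (s in seq_len(plan$n_samples[[g]])) {
      sid <- paste0(g, s)
      cnt <- stats::rmultinom(1, plan$cells_per_sample, leaf_props[[g]])[, 1]
      rows[[sid]] <- data.frame(
        sample_id = sid, group = g,
        leaf = rep(leaf_levels, cnt),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  n <- nrow(cells)
  cells$cell_id <- sprintf("cell%05d", seq_len(n))
  cells$main <- ifelse(cells$leaf %in% subs, plan$sub_main, cells$leaf)

  # --- latent coordinates (parent reduction) --------------------------------
  d <- plan$latent_dim
  main_centers <- matrix(0, length(mains), d, dimnames = list(mains))
  for (m in seq_along(mains)) main_centers[m, m] <- plan$separation_main
  sub_dirs <- matrix(0, length(subs), d, dimnames = list(subs))
  for (j in seq_along(subs)) {
    dim_j <- length(mains) + 1L + (j - 1L) %/% 2L
    sub_dirs[j, dim_j] <- plan$separation_sub * (-1)^(j - 1L)
  }
  centers <- main_centers[cells$main, , drop = FALSE]
  is_sub <- cells$leaf %in% subs
  centers[is_sub, ] <- centers[is_sub, , drop = FALSE] +
    sub_dirs[cells$leaf[is_sub], , drop = FALSE]
  latent <- centers + matrix(stats::rnorm(n * d), n, d)
  rownames(latent) <- cells$cell_id

  # --- child reduction: subpopulations resolved, units mis-scaled ----------
  child_ids <- cells$cell_id[is_sub]
  child_centers <- matrix(0, length(subs), d, dimnames = list(subs))
  for (j in seq_along(subs)) child_centers[j, j] <- plan$separation_child
  nc <- length(child_ids)
  child_coords <- (child_centers[cells$leaf[is_sub], , drop = FALSE] +
                   matrix(stats::rnorm(nc * d), nc, d)) * plan$child_scale
  rownames(child_coords) <- child_ids

  # --- counts: gamma-Poisson with planted markers --------------------------
  lambda <- stats::rlnorm(plan$n_genes, meanlog = log(0.2), sdlog = 1.2)
  lambda <- lambda * plan$library_size / sum(lambda)
  genes <- sprintf("gene%03d", seq_len(plan$n_genes))
  fold <- matrix(1, plan$n_genes, length(leaf_levels),
                 dimnames = list(genes, leaf_levels))
  marker_rows <- list()
  next_gene <- 1L
  for (cl in leaf_levels) {
    ix <- next_gene:(next_gene + plan$markers_per_cluster - 1L)
    fold[ix, cl] <- plan$marker_fold
    marker_rows[[cl]] <- data.frame(cluster = cl, gene = genes[ix],
                                    fold = plan$marker_fold,
                                    stringsAsFactors = FALSE)
    next_gene <- next_gene + plan$markers_per_cluster
  }
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL

  mu <- lambda * fold[, cells$leaf, drop = FALSE]   # genes x cells
  ds_gene <- NULL
  if (!is.null(plan$ds_effect)) {
    eff <- plan$ds_effect
    ds_gene <- eff$gene
    if (is.null(ds_gene)) {
      candidates <- setdiff(genes, markers$gene)
      ds_gene <- candidates[which.max(lambda[match(candidates, genes)])]
    }
    hit <- (cells$leaf == eff$cluster | cells$main == eff$cluster) &
      cells$group == eff$group
    mu[ds_gene, hit] <- mu[ds_gene, hit] * eff$fold
  }
  size_factor <- stats::rlnorm(n, meanlog = 0, sdlog = 0.1)
  mu <- sweep(mu, 2, size_factor, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = plan$dispersion),
                   nrow = plan$n_genes,
                   dimnames = list(genes, cells$cell_id))
  expr <- as_sparse_counts(counts)

  # --- assemble the hierarchy ----------------------------------------------
  parent_cells <- data.frame(cell_id = cells$cell_id,
                             sample_id = cells$sample_id,
                             group = cells$group, cluster = cells$main,
                             stringsAsFactors = FALSE)
  parent <- create_pi(expr, parent_cells, reductions = list(pca = latent))

  child_cells <- data.frame(cell_id = child_ids,
                            sample_id = cells$sample_id[is_sub],
                            group = cells$group[is_sub],
                            cluster = cells$leaf[is_sub],
                            stringsAsFactors = FALSE)
  child <- create_pi(expr[, child_ids, drop = FALSE], child_cells,
                     reductions = list(pca = child_coords))
  child_name <- paste0(plan$sub_main, "sub")
  parent <- attach_subcluster(parent, child_name, child_ids, child)

  if (isTRUE(plan$compute_embedding)) {
    g <- build_knn(parent, "pca", k = plan$k)
    parent$reductions[["umap"]] <-
      embed_merged(g, reprojection_config(k = plan$k, seed = plan$seed))
  }

  realized <- table(cells$sample_id, cells$leaf)
  truth <- list(
    cells = cells[c("cell_id", "sample_id", "group", "main", "leaf")],
    leaf_levels = leaf_levels,
    sub_levels = subs,
    child_name = child_name,
    planned_props = leaf_props,
    realized_counts = realized,
    markers = markers,
    ds_gene = ds_gene,
    plan = plan
  )
  list(pi = parent, truth = truth)
}

#' Simulate a multi-sample compositional design (metadata-focused)
#'
#' A lightweight generator for cell-proportion scenarios: compartments
#' (main clusters) with group-dependent proportions, one compartment split
#' into subpopulations, per-sample multinomial sampling with optional
#' between-sample (lognormal) variability of the compartment proportions.
#' Expression is a single all-zero gene since only counts and labels matter
#' here. Useful for studying how the choice of reference population changes
#' conclusions, e.g. a lymphopenia-like global shrinkage of the T
#' compartment with constant within-compartment composition.
#'
#' @param seed Integer seed.
#' @param n_per_group Samples per group.
#' @param cells_per_sample Cells per sample.
#' @param comp_props Per-group named list of compartment proportions.
#' @param sub_comp Compartment that is subclustered.
#' @param sub_props Per-group named list of within-compartment proportions.
#' @param sample_cv Lognormal sd perturbing each sample's compartment
#'   proportions (between-sample variability).
#' @param sub_cv Same for the within-compartment proportions.
#' @return List with `pi` (hierarchy, child `"<sub_comp>sub"`) and `truth`.
#' @export
simulate_composition <- function(seed = 1, n_per_group = 8,
                                 cells_per_sample = 1000,
                                 comp_props = list(
                                   A = c(T = 0.6, B = 0.25, Mono = 0.15),
                                   B = c(T = 0.6, B = 0.25, Mono = 0.15)),
                                 sub_comp = "T",
                                 sub_props = list(
                                   A = c(Treg_naive = 0.1, Treg_mem = 0.1,
                                         Tconv = 0.8),
                                   B = c(Treg_naive = 0.1, Treg_mem = 0.1,
                                         Tconv = 0.8)),
                                 sample_cv = 0.15, sub_cv = 0) {
  set.seed(seed)
  groups <- names(comp_props)
  comps <- names(comp_props[[1]])
  subs <- names(sub_props[[1]])
  rows <- list()
  for (g in groups) {
    for (s in seq_len(n_per_group)) {
      sid <- paste0(g, s)
      p <- comp_props[[g]] * stats::rlnorm(length(comps), 0, sample_cv)
      p <- p / sum(p)
      cnt <- stats::rmultinom(1, cells_per_sample, p)[, 1]
      comp_lab <- rep(comps, cnt)
      leaf <- comp_lab
      n_sub <- sum(comp_lab == sub_comp)
      if (n_sub > 0) {
        ps <- sub_props[[g]] * stats::rlnorm(length(subs), 0, sub_cv)
        ps <- ps / sum(ps)
        scnt <- stats::rmultinom(1, n_sub, ps)[, 1]
        leaf[comp_lab == sub_comp] <- rep(subs, scnt)
      }
      rows[[sid]] <- data.frame(sample_id = sid, group = g, main = comp_lab,
                                leaf = leaf, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  n <- nrow(cells)
  cells$cell_id <- sprintf("cell%06d", seq_len(n))

  expr <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1L, n),
                               dimnames = list("gene001", cells$cell_id))
  parent <- create_pi(expr,
                      data.frame(cell_id = cells$cell_id,
                                 sample_id = cells$sample_id,
                                 group = cells$group, cluster = cells$main,
                                 stringsAsFactors = FALSE))
  in_sub <- cells$main == sub_comp
  child_ids <- cells$cell_id[in_sub]
  child <- create_pi(expr[, child_ids, drop = FALSE],
                     data.frame(cell_id = child_ids,
                                sample_id = cells$sample_id[in_sub],
                                group = cells$group[in_sub],
                                cluster = cells$leaf[in_sub],
                                stringsAsFactors = FALSE))
  parent <- attach_subcluster(parent, paste0(sub_comp, "sub"), child_ids,
                              child)
  list(pi = parent,
       truth = list(cells = cells, comp_props = comp_props,
                    sub_props = sub_props, sub_comp = sub_comp,
                    child_name = paste0(sub_comp, "sub")))
}
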