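make_expr_pi <- function(mat, clusters, sample_id = "s1", group = "A") {
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  n <- ncol(mat)
  ids <- sprintf("c%03d", seq_len(n))
  colnames(mat) <- ids
  create_pi(mat, data.frame(cell_id = ids,
                            sample_id = rep_len(sample_id, n),
                            group = rep_len(group, n),
                            cluster = clusters,
                            stringsAsFactors = FALSE))
}

test_that("expression frequency counts detected cells exactly", {
  # 3 genes x 8 cells, clusters of 4; hand-set nonzeros
  mat <- rbind(c(1, 2, 3, 0, 5, 5, 5, 5),   # 3/4 in k1, 4/4 in k2
               rep(0, 8),                    # never detected
               c(1, 1, 1, 1, 0, 0, 0, 0))   # all of k1, none of k2
  pi <- make_expr_pi(mat, rep(c("k1", "k2"), each = 4))
  freq <- expression_frequency(pi)
  expect_equal(freq["g1", ], c(k1 = 0.75, k2 = 1))
  expect_equal(unname(freq["g2", ]), c(0, 0))
  expect_equal(freq["g3", ], c(k1 = 1, k2 = 0))
  expect_true(all(freq >= 0 & freq <= 1))
})

test_that("expression frequency only depends on the zero pattern", {
  set.seed(10)
  mat <- matrix(rpois(200, 0.8), 10, 20)
  pi1 <- make_expr_pi(mat, rep_len(c("a", "b"), 20))
  pi2 <- make_expr_pi(mat * 1000 + (mat > 0) * 0.123,
                      rep_len(c("a", "b"), 20))
  expect_equal(expression_frequency(pi1), expression_frequency(pi2))
})

test_that("planted markers rank first and label swaps swap marker sets", {
  fix <- generate_fixture(fixture_plan(seed = 2, cells_per_sample = 30,
                                       compute_embedding = FALSE))
  mk <- find_markers(fix$pi, level = "current")
  planted <- fix$truth$markers
  for (cl in c("B", "Mono")) {
    top <- mk$gene[mk$cluster == cl][1]
    expect_true(top %in% planted$gene[planted$cluster == cl])
  }

  # swapping two cluster labels swaps their marker tables
  pi_sw <- fix$pi
  sw <- pi_sw$cells$cluster
  pi_sw$cells$cluster <- ifelse(sw == "B", "Mono",
                                ifelse(sw == "Mono", "B", sw))
  mk_sw <- find_markers(pi_sw, level = "current")
  expect_equal(mk$gene[mk$cluster == "B"],
               mk_sw$gene[mk_sw$cluster == "Mono"])
  expect_equal(mk$p_adj[mk$cluster == "B"],
               mk_sw$p_adj[mk_sw$cluster == "Mono"])
})

test_that("identical expression in all clusters yields no markers", {
  mat <- matrix(rep(c(5, 1, 0, 2), each = 12), nrow = 4, byrow = TRUE)
  pi <- make_expr_pi(mat, rep_len(c("a", "b", "c"), 12))
  mk <- suppressWarnings(find_markers(pi))
  expect_true(all(mk$p_adj >= 0.05))
})

test_that("tiny clusters are skipped with a warning", {
  set.seed(1)
  mat <- matrix(rpois(48, 2), 4, 12)
  pi <- make_expr_pi(mat, c(rep("big", 10), "small", "small"))
  expect_warning(mk <- find_markers(pi), "fewer than")
  expect_false("small" %in% mk$cluster)
})

test_that("pseudobulk sums are exact and conserved", {
  # 3-sample toy with hand-assigned cells
  mat <- matrix(1:24, 4, 6)
  pi <- make_expr_pi(mat, clusters = c("x", "x", "y", "y", "y", "x"),
                     sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"))
  pb <- pseudobulk(pi)
  expect_equal(pb$counts[, "s1|x"], rowSums(mat[, 1:2]),
               ignore_attr = TRUE)
  expect_equal(pb$counts[, "s1|y"], mat[, 3], ignore_attr = TRUE)
  expect_equal(pb$counts[, "s2|y"], rowSums(mat[, 4:5]),
               ignore_attr = TRUE)
  expect_equal(pb$counts[, "s3|x"], mat[, 6], ignore_attr = TRUE)
  expect_equal(sum(pb$counts), sum(mat))
  expect_equal(pb$coldata$n_cells[pb$coldata$sample_id == "s1" &
                                    pb$coldata$cluster == "x"], 2L)

  # degenerate: one sample, one cluster -> row sums
  pi1 <- make_expr_pi(mat, rep("only", 6))
  pb1 <- pseudobulk(pi1)
  expect_equal(ncol(pb1$counts), 1L)
  expect_equal(pb1$counts[, 1], rowSums(mat), ignore_attr = TRUE)
})

test_that("differential state is antisymmetric and refuses n < 2", {
  set.seed(20)
  fix <- generate_fixture(fixture_plan(
    seed = 20, n_samples = c(A = 3, B = 3), cells_per_sample = 80,
    compute_embedding = FALSE,
    ds_effect = list(cluster = "Mono", group = "B", fold = 4)))
  pb <- pseudobulk(fix$pi)
  ds_ab <- differential_state(pb, "Mono", c("A", "B"))
  ds_ba <- differential_state(pb, "Mono", c("B", "A"))
  m <- match(ds_ab$gene, ds_ba$gene)
  expect_equal(ds_ab$log2fc, -ds_ba$log2fc[m])
  expect_equal(ds_ab$p, ds_ba$p[m])
  # the planted gene is shifted in the right direction
  expect_lt(ds_ab$log2fc[ds_ab$gene == fix$truth$ds_gene], 0)

  # identical profiles in both groups -> all log fold-changes zero
  cnt <- matrix(rep(c(10, 5, 0, 2), 4), 4, 4)
  rownames(cnt) <- paste0("g", 1:4)
  pbm <- structure(list(
    counts = cnt,
    coldata = data.frame(sample_id = paste0("s", 1:4), cluster = "k",
                         group = c("A", "A", "B", "B"), n_cells = 5L)),
    class = "pseudobulk")
  ds0 <- differential_state(pbm, "k", c("A", "B"))
  expect_true(all(ds0$log2fc == 0))

  one <- pbm
  one$coldata$group <- c("A", "B", "B", "B")
  expect_error(differential_state(one, "k", c("A", "B")), "replication")
})

test_that("proportions: self-reference is 1 and the chain rule is exact", {
  sim <- simulate_composition(seed = 31, n_per_group = 4,
                              cells_per_sample = 300)
  pi <- sim$pi

  # target = reference: every proportion is exactly 1
  tab_self <- cell_proportions(pi, target = "Tconv",
                               reference = "Tsub", mode = "unpooled")
  sub <- tab_self[tab_self$cluster == "Tconv", ]
  t_only <- cell_proportions(pi, target = "Tsub", reference = "Tsub",
                             mode = "unpooled")
  agg <- stats::aggregate(proportion ~ sample_id, as.data.frame(t_only),
                          sum)
  expect_true(all(agg$proportion == 1))

  # chain rule: prop(subset | all) = prop(subset | T) * prop(T | all)
  vs_all <- cell_proportions(pi, target = "Treg_naive", mode = "unpooled")
  vs_t <- cell_proportions(pi, target = "Treg_naive", reference = "Tsub",
                           mode = "unpooled")
  t_vs_all <- cell_proportions(pi, target = "T", mode = "unpooled")
  m1 <- match(vs_all$sample_id, vs_t$sample_id)
  m2 <- match(vs_all$sample_id, t_vs_all$sample_id)
  expect_identical(vs_all$count, vs_t$count[m1])
  expect_equal(vs_all$proportion,
               vs_t$proportion[m1] * t_vs_all$proportion[m2],
               tolerance = 1e-12)

  # containment is enforced
  expect_error(cell_proportions(pi, target = "B", reference = "Tsub"),
               "not contained")
})

test_that("realized sample compositions match the generator's plan", {
  fix <- generate_fixture(fixture_plan(seed = 8, cells_per_sample = 60,
                                       compute_embedding = FALSE))
  tab <- cell_proportions(fix$pi, target = fix$truth$child_name,
                          reference = "T", mode = "unpooled")
  # per-sample realized within-T fractions stay inside exact binomial
  # 99.9% bounds around the planned fraction
  for (i in seq_len(nrow(tab))) {
    g <- tab$group[i]
    p_true <- fix$truth$plan$sub_props[[g]][[tab$cluster[i]]]
    ci <- stats::binom.test(tab$count[i], tab$ref_count[i],
                            p_true)$p.value
    expect_gt(ci, 1e-4)
  }
})

test_that("pooled tables plot as full compositions and refuse testing", {
  sim <- simulate_composition(seed = 5, n_per_group = 3,
                              cells_per_sample = 200)
  pooled <- cell_proportions(sim$pi, target = c("T", "B", "Mono"),
                             mode = "pooled")
  sums <- tapply(pooled$proportion, pooled$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(test_proportions(pooled), "unpooled")

  p <- plot_proportions(pooled)
  expect_s3_class(p, "ggplot")
  bars <- ggplot2::ggplot_build(p)$data[[1]]
  expect_equal(as.numeric(tapply(bars$ymax - bars$ymin, bars$x, sum)),
               rep(1, 2), tolerance = 1e-12)
})

test_that("group testing on proportions behaves at the extremes", {
  sim <- simulate_composition(seed = 42, n_per_group = 6,
                              cells_per_sample = 400)
  tab <- cell_proportions(sim$pi, target = "Tsub", reference = "Tsub",
                          mode = "unpooled")
  tested <- test_proportions(tab)
  res <- attr(tested, "test")
  expect_identical(sort(res$cluster),
                   sort(unique(tab$cluster)))
  expect_true(all(res$p >= 0 & res$p <= 1))

  # a strong planted shift is detected
  shift <- simulate_composition(
    seed = 43, n_per_group = 8, cells_per_sample = 500,
    sub_props = list(A = c(Treg_naive = 0.10, Treg_mem = 0.1, Tconv = 0.8),
                     B = c(Treg_naive = 0.30, Treg_mem = 0.1,
                           Tconv = 0.6)))
  tab2 <- cell_proportions(shift$pi, target = "Tsub", reference = "Tsub",
                           mode = "unpooled")
  res2 <- attr(test_proportions(tab2), "test")
  expect_lt(res2$p_adj[res2$cluster == "Treg_naive"], 0.05)

  # identical per-sample proportion vectors give p = 1
  flat <- tab2[tab2$cluster == "Treg_naive", ]
  flat$proportion <- 0.5
  attr(flat, "mode") <- "unpooled"
  class(flat) <- c("proportion_table", "data.frame")
  res3 <- attr(test_proportions(flat), "test")
  expect_equal(res3$p, 1)

  # annotation shows up on the unpooled plot
  p <- plot_proportions(test_proportions(tab2))
  expect_s3_class(p, "ggplot")
})

test_that("run_quantification fills the analysis slots", {
  fix <- generate_fixture(fixture_plan(seed = 12, cells_per_sample = 30,
                                       compute_embedding = FALSE))
  pi <- run_quantification(fix$pi)
  expect_false(is.null(pi$exp_freq))
  expect_false(is.null(pi$markers))
  expect_equal(sort(colnames(pi$exp_freq)),
               sort(unique(pi$cells$cluster)))
})
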