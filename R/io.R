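#' Write a Pi object (and its hierarchy) to a directory
#'
#' Serializes one object per directory in language-agnostic plain-text
#' formats: `matrix.mtx` + `features.tsv` + `barcodes.tsv` (10x-style
#' triplet), `cells.tsv` metadata, one CSV per reduction under
#' `reductions/`, one edge-list TSV per neighbor graph under `graphs/`,
#' filled analysis slots as TSV, and a `manifest.json` tying everything
#' together. Children recurse into `children/<name>/`, so a multi-level
#' hierarchy is a directory tree.
#'
#' @param pi A `pi_obj`.
#' @param dir Target directory (created; must not already contain an
#'   object unless `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing object directory.
#' @return `dir`, invisibly.
#' @export
write_pi <- function(pi, dir, overwrite = FALSE) {
  stopifnot(inherits(pi, "pi_obj"))
  if (file.exists(file.path(dir, "manifest.json")) && !overwrite) {
    stop("'", dir, "' already holds an object; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(pi$expression, file.path(dir, "matrix.mtx"))
  writeLines(rownames(pi$expression), file.path(dir, "features.tsv"))
  writeLines(pi$cells$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.table(pi$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (length(pi$reductions)) {
    dir.create(file.path(dir, "reductions"), showWarnings = FALSE)
    for (nm in names(pi$reductions)) {
      mat <- pi$reductions[[nm]]
      df <- data.frame(cell_id = rownames(mat), mat, check.names = FALSE,
                       row.names = NULL)
      utils::write.csv(df, file.path(dir, "reductions",
                                     paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  if (length(pi$neighbor_graphs)) {
    dir.create(file.path(dir, "graphs"), showWarnings = FALSE)
    for (nm in names(pi$neighbor_graphs)) {
      write_graph_tsv(pi$neighbor_graphs[[nm]],
                      file.path(dir, "graphs", paste0(nm, ".tsv")))
    }
  }

  if (!is.null(pi$exp_freq)) {
    utils::write.table(data.frame(gene = rownames(pi$exp_freq), pi$exp_freq,
                                  check.names = FALSE),
                       file.path(dir, "exp_freq.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(pi$markers)) {
    utils::write.table(pi$markers, file.path(dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(pi$ds)) {
    write_annotated_tsv(pi$ds, file.path(dir, "ds.tsv"))
  }
  if (length(pi$cell_prop)) {
    dir.create(file.path(dir, "cell_prop"), showWarnings = FALSE)
    for (nm in names(pi$cell_prop)) {
      write_proportions(pi$cell_prop[[nm]],
                        file.path(dir, "cell_prop", paste0(nm, ".tsv")))
    }
  }

  for (nm in names(pi$children)) {
    link <- pi$children[[nm]]
    cdir <- file.path(dir, "children", nm)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(cell_id = link$cell_ids,
                 child_label = unname(link$label_map[link$cell_ids])),
      file.path(cdir, "link.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_pi(link$child, file.path(cdir, "object"), overwrite = overwrite)
  }

  manifest <- list(
    format = "pi-directory", version = 1L,
    n_genes = nrow(pi$expression), n_cells = nrow(pi$cells),
    reductions = as.list(names(pi$reductions)),
    graphs = as.list(names(pi$neighbor_graphs)),
    slots = list(exp_freq = !is.null(pi$exp_freq),
                 markers = !is.null(pi$markers),
                 ds = !is.null(pi$ds),
                 cell_prop = as.list(names(pi$cell_prop))),
    children = as.list(names(pi$children)),
    has_parent = !is.null(pi$parent)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a Pi object (and its hierarchy) from a directory
#'
#' Inverse of [write_pi()]: restores cell order, labels, reductions,
#' neighbor graphs, analysis slots and the full child topology. Children are
#' re-attached through [attach_subcluster()], so all link invariants are
#' re-validated on read.
#'
#' @param dir Directory written by [write_pi()].
#' @return A `pi_obj`.
#' @export
read_pi <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("'", dir, "' does not contain a serialized object ",
         "(manifest.json missing)", call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)

  expr <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                      "CsparseMatrix")
  rownames(expr) <- readLines(file.path(dir, "features.tsv"))
  colnames(expr) <- readLines(file.path(dir, "barcodes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, colClasses = "character")

  reductions <- list()
  for (nm in unlist(manifest$reductions)) {
    df <- utils::read.csv(file.path(dir, "reductions", paste0(nm, ".csv")),
                          colClasses = c(cell_id = "character"))
    mat <- as.matrix(df[-1])
    rownames(mat) <- df$cell_id
    reductions[[nm]] <- mat
  }

  pi <- create_pi(expr, cells, reductions)

  for (nm in unlist(manifest$graphs)) {
    pi$neighbor_graphs[[nm]] <-
      read_graph_tsv(file.path(dir, "graphs", paste0(nm, ".tsv")),
                     pi$cells$cell_id)
  }

  if (isTRUE(manifest$slots$exp_freq)) {
    df <- utils::read.table(file.path(dir, "exp_freq.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE)
    pi$exp_freq <- as.matrix(df[-1])
    rownames(pi$exp_freq) <- df$gene
  }
  if (isTRUE(manifest$slots$markers)) {
    pi$markers <- utils::read.table(file.path(dir, "markers.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  }
  if (isTRUE(manifest$slots$ds)) {
    pi$ds <- read_annotated_tsv(file.path(dir, "ds.tsv"))
  }
  for (nm in unlist(manifest$slots$cell_prop)) {
    pi$cell_prop[[nm]] <-
      read_proportions(file.path(dir, "cell_prop", paste0(nm, ".tsv")))
  }

  for (nm in unlist(manifest$children)) {
    cdir <- file.path(dir, "children", nm)
    link <- utils::read.table(file.path(cdir, "link.tsv"), sep = "\t",
                              header = TRUE, colClasses = "character")
    child <- read_pi(file.path(cdir, "object"))
    pi <- attach_subcluster(pi, nm, link$cell_id, child)
  }
  pi
}

# --- small TSV helpers with '#'-comment parameter headers -------------------

write_annotated_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attributes(df)
  for (key in setdiff(names(meta), c("names", "row.names", "class"))) {
    writeLines(sprintf("# %s=%s", key,
                       paste(meta[[key]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_annotated_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub("=.*", "", kv)
    val <- strsplit(sub("^[^=]*=", "", kv), ",", fixed = TRUE)[[1]]
    attr(df, key) <- val
  }
  df
}

#' Write a proportion table as annotated TSV
#'
#' The header comment lines record the table's parameters (mode, reference,
#' target, and any attached test results).
#'
#' @param tab A `proportion_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(tab, path) {
  stopifnot(inherits(tab, "proportion_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s", attr(tab, "mode")), con)
  writeLines(sprintf("# reference=%s", attr(tab, "reference")), con)
  writeLines(sprintf("# target=%s", attr(tab, "target")), con)
  test <- attr(tab, "test")
  if (!is.null(test)) {
    writeLines(sprintf("# test=wilcoxon-rank-sum;adjust=BH;groups=%s",
                       paste(attr(tab, "groups"), collapse = ",")), con)
    writeLines(sprintf("# test_result=%s:%.17g:%.17g:%.17g", test$cluster,
                       test$statistic, test$p, test$p_adj), con)
  }
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a proportion table written by [write_proportions()]
#' @param path Annotated TSV file.
#' @return A `proportion_table`.
#' @export
read_proportions <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(cluster = "character"))
  get1 <- function(key) {
    h <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(h)) sub(paste0("^# ", key, "="), "", h[1]) else NULL
  }
  out <- structure(df, class = c("proportion_table", "data.frame"),
                   mode = get1("mode"), reference = get1("reference"),
                   target = get1("target"))
  res_lines <- grep("^# test_result=", hdr, value = TRUE)
  if (length(res_lines)) {
    parts <- strsplit(sub("^# test_result=", "", res_lines), ":",
                      fixed = TRUE)
    attr(out, "test") <- data.frame(
      cluster = vapply(parts, `[`, "", 1),
      statistic = as.numeric(vapply(parts, `[`, "", 2)),
      p = as.numeric(vapply(parts, `[`, "", 3)),
      p_adj = as.numeric(vapply(parts, `[`, "", 4)),
      stringsAsFactors = FALSE)
    attr(out, "groups") <- strsplit(
      sub(".*groups=", "", grep("^# test=", hdr, value = TRUE)[1]),
      ",", fixed = TRUE)[[1]]
  }
  out
}

#' Write an embedding as CSV
#' @param pi A `pi_obj`.
#' @param reduction Reduction name.
#' @param path Output CSV (`cell_id`, coordinate columns).
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(pi, reduction, path) {
  mat <- pi$reductions[[reduction]]
  if (is.null(mat)) stop("reduction '", reduction, "' not found",
                         call. = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(mat), mat,
                              check.names = FALSE, row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
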