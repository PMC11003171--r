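## Readers and writers for the external formats: Matrix Market MTX with
## plain-text label files, dense TSV, H5AD (bridged through a Python
## anndata interpreter when one is available), crosstab TSV networks,
## edge lists, and the posterior output bundle.

mtx_label_paths <- function(path) {
  base <- sub("\\.mtx$", "", path)
  list(rows = paste0(base, "_rows.txt"), cols = paste0(base, "_cols.txt"))
}

#' Read a cells-by-genes expression matrix
#'
#' Supported formats: `mtx` (Matrix Market sparse file with companion
#' `<base>_rows.txt` / `<base>_cols.txt` label files, one label per
#' line), `tsv` (dense, first column = row labels, header = column
#' labels), and `h5ad` (converted via the `python` interpreter's anndata
#' module, which must be on the PATH; the `X` matrix is read as counts).
#' `format = "auto"` dispatches on the file extension.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"mtx"`, `"tsv"`, `"h5ad"`.
#' @param transpose set `TRUE` for genes x cells inputs.
#' @param row_labels,col_labels optional label-file overrides for MTX.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv", "h5ad"),
                            transpose = FALSE,
                            row_labels = NULL, col_labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", tsv = "tsv", txt = "tsv",
                     h5ad = "h5ad",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "h5ad") {
    tmp <- h5ad_to_mtx(path)
    on.exit(unlink(dirname(tmp$mtx), recursive = TRUE), add = TRUE)
    return(read_expression(tmp$mtx, "mtx", transpose = transpose))
  }
  if (format == "mtx") {
    lp <- mtx_label_paths(path)
    if (is.null(row_labels)) row_labels <- lp$rows
    if (is.null(col_labels)) col_labels <- lp$cols
    m <- as.matrix(Matrix::readMM(path))
    rl <- readLines(row_labels)
    cl <- readLines(col_labels)
    if (length(rl) != nrow(m))
      stop("row label count (", length(rl), ") != matrix rows (",
           nrow(m), ")")
    if (length(cl) != ncol(m))
      stop("column label count (", length(cl), ") != matrix columns (",
           ncol(m), ")")
    dimnames(m) <- list(rl, cl)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
  }
  if (transpose) m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix
#'
#' `mtx` writes a Matrix Market file plus `<base>_rows.txt` and
#' `<base>_cols.txt` label files; `tsv` writes a dense table with row
#' labels in the first column.
#'
#' @param W an expression matrix.
#' @param path output file (`.mtx` or `.tsv`).
#' @param format `"auto"` (from extension), `"mtx"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(W, path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  W <- as_expression(W)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(W), sparse = TRUE), path)
    lp <- mtx_label_paths(path)
    writeLines(rownames(W), lp$rows)
    writeLines(colnames(W), lp$cols)
  } else {
    write_crosstab(unclass(W), path, first_col = "cell_id")
  }
  invisible(path)
}

h5ad_to_mtx <- function(path) {
  py <- Sys.which("python")
  if (py == "")
    stop("h5ad input requires a `python` interpreter with anndata on PATH")
  out_dir <- tempfile("h5ad_bridge_")
  dir.create(out_dir)
  mtx <- file.path(out_dir, "X.mtx")
  script <- sprintf(
    "import anndata, scipy.io, scipy.sparse as sp\nad = anndata.read_h5ad(%s)\nX = ad.X if sp.issparse(ad.X) else sp.csr_matrix(ad.X)\nscipy.io.mmwrite(%s, X)\nopen(%s, 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')\nopen(%s, 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')\n",
    deparse(path), deparse(mtx),
    deparse(file.path(out_dir, "X_rows.txt")),
    deparse(file.path(out_dir, "X_cols.txt")))
  sf <- file.path(out_dir, "convert.py")
  writeLines(script, sf)
  status <- system2(py, sf, stdout = FALSE, stderr = "")
  if (status != 0) stop("h5ad conversion failed (python exit ", status, ")")
  list(mtx = mtx)
}

write_crosstab <- function(m, path, first_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(first_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_crosstab <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  rn <- as.character(df[[1]])
  if (anyDuplicated(rn)) stop("duplicate row labels in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate column labels in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' Read a binary network from a crosstab TSV
#'
#' Genes in rows, TFs in columns, numeric entries; any entry with
#' `|value| > 0` becomes an edge, so signed networks (repression coded
#' negative) binarize correctly.
#'
#' @param path crosstab TSV file.
#' @return a [prior_network()].
#' @export
read_network_crosstab <- function(path) {
  m <- read_crosstab(path)
  prior_network((abs(m) > 0) * 1)
}

#' Write a network (or any labelled matrix) as a crosstab TSV
#'
#' @param m genes x TFs matrix with labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_crosstab <- function(m, path) {
  write_crosstab(as.matrix(m), path)
}

#' Read a network from an edge list
#'
#' Three-column TSV `gene`, `tf`, `value` (header optional, detected from
#' a non-numeric third field on line one). Converted to a binary
#' crosstab; missing pairs are zero.
#'
#' @param path edge-list file.
#' @return a [prior_network()].
#' @export
read_network_edgelist <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1)
  has_header <- is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.delim(path, header = has_header)
  if (ncol(df) < 3) stop("edge list needs gene, tf, value columns")
  genes <- sort(unique(as.character(df[[1]])))
  tfs <- sort(unique(as.character(df[[2]])))
  m <- matrix(0, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  m[cbind(as.character(df[[1]]), as.character(df[[2]]))] <-
    (abs(as.numeric(df[[3]])) > 0) * 1
  prior_network(m)
}

#' Reconcile gene labels between expression and prior matrices
#'
#' The model's gene axis is the lexicographically sorted intersection of
#' the expression and prior gene labels; the TF axis is the prior's.
#' Everything dropped from either side is reported. Input order never
#' affects the result.
#'
#' @param W cells x genes expression matrix.
#' @param prior genes x TFs network.
#' @return object of class `"pmfgrn_reconciliation"`: list with
#'   `shared_genes`, `expression_index_map`, `prior_index_map`,
#'   `dropped_from_expression`, `dropped_from_prior`.
#' @export
reconcile_labels <- function(W, prior) {
  W <- as_expression(W)
  prior <- as_network(prior)
  shared <- sort(intersect(colnames(W), rownames(prior)))
  if (!length(shared))
    stop("no genes shared between expression (", ncol(W),
         " genes) and prior (", nrow(prior), " genes)")
  structure(list(
    shared_genes = shared,
    expression_index_map = match(shared, colnames(W)),
    prior_index_map = match(shared, rownames(prior)),
    dropped_from_expression = sort(setdiff(colnames(W), shared)),
    dropped_from_prior = sort(setdiff(rownames(prior), shared))),
    class = "pmfgrn_reconciliation")
}

#' @method print pmfgrn_reconciliation
#' @export
print.pmfgrn_reconciliation <- function(x, ...) {
  cat(sprintf(
    "label reconciliation: %d shared genes (%d dropped from expression, %d from prior)\n",
    length(x$shared_genes), length(x$dropped_from_expression),
    length(x$dropped_from_prior)))
  invisible(x)
}

#' Write a posterior summary bundle
#'
#' Writes `A_mean.tsv`, `A_var.tsv`, `B_mean.tsv` (genes x TFs
#' crosstabs), `tfa.tsv` (cells x TFs), `edges.tsv` (the thresholded edge
#' list) and `run_meta.yaml` (configuration, seeds, stopping step) into a
#' directory.
#'
#' @param summary a `summary.pmfgrn` (or compatible list).
#' @param out_dir output directory, created if missing.
#' @param threshold probability cut for `edges.tsv`.
#' @return `out_dir`, invisibly.
#' @export
write_posterior <- function(summary, out_dir, threshold = 0.9) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  write_crosstab(summary$A_mean, file.path(out_dir, "A_mean.tsv"))
  write_crosstab(summary$A_var, file.path(out_dir, "A_var.tsv"))
  write_crosstab(summary$B_mean, file.path(out_dir, "B_mean.tsv"))
  write_crosstab(summary$tfa, file.path(out_dir, "tfa.tsv"),
                 first_col = "cell_id")
  edges <- threshold_network(summary, threshold)
  utils::write.table(edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- summary$meta
  meta_out <- list(seed = meta$seed, mc_samples = meta$mc_samples,
                   stopped_at = meta$stopped_at,
                   stop_reason = meta$stop_reason,
                   stopping = meta$stopping,
                   best_metric = meta$best_metric,
                   best_step = meta$best_step,
                   threshold = threshold,
                   config = unclass(meta$config))
  yaml::write_yaml(meta_out, file.path(out_dir, "run_meta.yaml"))
  invisible(out_dir)
}

#' Read back a posterior matrix written by [write_posterior()]
#'
#' @param path a crosstab TSV (e.g. `A_mean.tsv`).
#' @return labelled numeric matrix.
#' @export
read_posterior_matrix <- function(path) read_crosstab(path)
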