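#' Construct a cells-by-genes expression matrix
#'
#' Wraps a numeric matrix of raw UMI counts (cells in rows, genes in
#' columns) after validating it. Counts are used unnormalized throughout:
#' library-size variation is absorbed by the per-cell depth factor of the
#' model, not by preprocessing.
#'
#' @param values numeric matrix, N cells x M genes, non-negative, no NAs.
#' @param cell_ids,gene_ids character labels; default taken from `dimnames`.
#' @return a numeric matrix of class `"expression_matrix"` with dimnames set.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (any(values < 0)) stop("expression matrix contains negative values")
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("expression_matrix", class(matrix()))
  values
}

#' Construct a genes-by-TFs binary network matrix
#'
#' Container for prior-knowledge networks and gold standards: a strictly
#' binary matrix with target genes in rows and transcription factors in
#' columns. Signed inputs (e.g. repression coded as -1) must be binarized
#' before construction; the crosstab reader does this automatically.
#'
#' @param entries numeric matrix, M genes x K TFs, entries in {0, 1}.
#' @param gene_ids,tf_ids character labels; default taken from `dimnames`.
#' @return a numeric matrix of class `"prior_network"` with dimnames set.
#' @export
prior_network <- function(entries, gene_ids = rownames(entries),
                          tf_ids = colnames(entries)) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(entries)))
  if (is.null(tf_ids)) tf_ids <- paste0("tf_", seq_len(ncol(entries)))
  gene_ids <- as.character(gene_ids)
  tf_ids <- as.character(tf_ids)
  if (length(gene_ids) != nrow(entries))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(entries), ")")
  if (length(tf_ids) != ncol(entries))
    stop("tf_ids length (", length(tf_ids), ") != number of columns (",
         ncol(entries), ")")
  if (anyNA(entries)) stop("network matrix contains missing values")
  if (!all(entries %in% c(0, 1)))
    stop("network matrix must be strictly binary (0/1)")
  dimnames(entries) <- list(gene_ids, tf_ids)
  class(entries) <- c("prior_network", class(matrix()))
  entries
}

# Internal coercers: accept classed containers or plain labelled matrices.
as_expression <- function(W) {
  if (inherits(W, "expression_matrix")) return(W)
  expression_matrix(W)
}

as_network <- function(A) {
  if (inherits(A, "prior_network")) return(A)
  prior_network(A)
}

# A scored network is any finite numeric genes x TFs matrix with dimnames.
check_scored <- function(scores, arg = "scores") {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop(arg, " must carry gene (row) and TF (column) labels")
  if (!all(is.finite(scores))) stop(arg, " contains non-finite entries")
  scores
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes, total counts %.6g\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @method print prior_network
#' @export
print.prior_network <- function(x, ...) {
  cat(sprintf("prior_network: %d genes x %d TFs, %d edges (density %.4g)\n",
              nrow(x), ncol(x), sum(x != 0), mean(x != 0)))
  invisible(x)
}
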