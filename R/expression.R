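#' Read an expression matrix from TSV/CSV
#'
#' The matrix is held samples x features internally. With
#' `samples = "auto"` the orientation is chosen so that features outnumber
#' samples (the usual shape of expression cohorts), and the decision is
#' reported in a message.
#'
#' @param path Delimited file with a header row and an identifier column.
#' @param sep Field separator (tab by default; `","` for CSV).
#' @param samples `"rows"`, `"cols"` or `"auto"`.
#' @return Numeric matrix, samples in rows.
#' @export
read_expression <- function(path, sep = "\t", samples = c("auto", "rows", "cols")) {
  samples <- match.arg(samples)
  df <- read.delim(path, header = TRUE, sep = sep, check.names = FALSE,
                   row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (samples == "cols" || (samples == "auto" && nrow(m) > ncol(m))) {
    m <- t(m)
    if (samples == "auto")
      message("read_expression: transposed input (rows taken as features)")
  }
  m
}

#' Write an expression matrix (samples x features) as TSV
#' @param matrix Numeric matrix with dimnames.
#' @param path Output file.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(sample = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample labels (`sample<TAB>label`, no header)
#' @param path TSV file.
#' @return Named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = c("character", "integer"))
  stats::setNames(df[[2L]], df[[1L]])
}

#' Collapse probe columns to genes
#'
#' When several probes measure one gene, keeps the probe whose across-sample
#' mean expression is highest (ties: lexicographically first probe). The
#' retained measurements are unchanged; only the column is renamed to the
#' gene symbol.
#'
#' @param matrix Expression matrix, samples x probes.
#' @param map Probe-to-gene map: named character vector (`names` = probes) or
#'   a two-column data.frame `probe`, `gene`.
#' @return Expression matrix, samples x genes (columns ordered by gene name).
#' @export
collapse_probes <- function(matrix, map) {
  if (is.data.frame(map)) map <- stats::setNames(as.character(map[[2L]]),
                                                 as.character(map[[1L]]))
  unmapped <- setdiff(colnames(matrix), names(map))
  if (length(unmapped))
    en_stop("mapping", "probes missing from the map: %s",
            paste(head(unmapped, 10L), collapse = ", "))
  genes <- unname(map[colnames(matrix)])
  means <- colMeans(matrix)
  pick <- vapply(split(seq_len(ncol(matrix)), genes), function(ix) {
    best <- ix[means[ix] == max(means[ix])]
    best[order(colnames(matrix)[best])][1L]
  }, integer(1L))
  out <- matrix[, pick, drop = FALSE]
  colnames(out) <- names(pick)
  out[, order(colnames(out)), drop = FALSE]
}

#' Shift an expression matrix to be non-negative
#'
#' Subtracts the global matrix minimum from every cell, so the output
#' minimum is exactly 0 and all between-cell differences are preserved.
#'
#' @param matrix Numeric matrix.
#' @return Shifted matrix.
#' @export
nonnegative_shift <- function(matrix) {
  if (length(matrix) == 0L) en_stop("parameter", "matrix is empty")
  matrix - min(matrix)
}

#' Align an expression matrix to a network's vertices
#'
#' Restricts the matrix to genes present among the network vertices,
#' re-extracts the main connected component of the induced subgraph, and
#' orders the feature columns by that component's vertex order. This is the
#' dataset a graph-convolutional model trains on.
#'
#' @param matrix Expression matrix, samples x genes.
#' @param network A `similarity_network`.
#' @param labels Named 0/1 vector covering all samples.
#' @return A `graph_aligned_dataset`: list with `x` (samples x vertices),
#'   `y` (0/1 labels), `genes` and `network` (the aligned subnetwork).
#' @export
align_to_graph <- function(matrix, network, labels) {
  miss <- setdiff(rownames(matrix), names(labels))
  if (length(miss))
    en_stop("validation", "labels missing for sample(s): %s",
            paste(head(miss, 5L), collapse = ", "))
  y <- labels[rownames(matrix)]
  if (!all(y %in% c(0L, 1L)))
    en_stop("validation", "labels must be 0/1")
  inter <- intersect(colnames(matrix), network$vertices)
  if (length(inter) == 0L)
    en_stop("alignment", "no genes shared between matrix and network")
  keep <- network$edges$from %in% inter & network$edges$to %in% inter
  sub <- similarity_network(inter, network$edges[keep, , drop = FALSE],
                            threshold = network$threshold,
                            weighted = network$weighted)
  sub <- main_component(sub)
  genes <- sub$vertices
  message(sprintf("align_to_graph: %d/%d genes matched, main component %d",
                  length(inter), ncol(matrix), length(genes)))
  structure(list(x = matrix[, genes, drop = FALSE],
                 y = stats::setNames(as.integer(y), rownames(matrix)),
                 genes = genes, network = sub),
            class = "graph_aligned_dataset")
}
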