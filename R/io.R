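#' Read a gene-by-sample expression matrix from TSV
#'
#' Expected layout: first column gene identifiers, header row of sample
#' identifiers, tab-separated log2 values. Duplicated gene or sample
#' identifiers and non-finite values are rejected.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionTSV <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop("duplicated sample id '", hdr[duplicated(hdr)][1], "' in ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed expression matrix: ", path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene id '", genes[duplicated(genes)][1], "' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample id '", colnames(m)[duplicated(colnames(m))][1],
         "' in ", path)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("non-finite expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTSV <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Requires at least \code{sample_id}, \code{batch} and \code{group}
#' columns; optional columns (grade, response, timepoint, cluster) pass
#' through untouched.
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
readAnnotationTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in ", path)
  df
}

#' @rdname readAnnotationTSV
#' @param annotation A sample annotation data.frame.
#' @export
writeAnnotationTSV <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column edge list as a graph
#'
#' @param path Path to a TSV with two columns (endpoint identifiers; a
#'   header row is expected). For directed graphs the first column is the
#'   parent (source) and the second the child (target).
#' @param directed Logical; build a directed graph?
#' @return An \code{igraph} graph. Self-loops and duplicate edges are
#'   removed so the result is simple.
#' @export
readEdgeListTSV <- function(path, directed = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L)
    stop("empty or malformed edge list: ", path)
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = directed)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' @rdname readEdgeListTSV
#' @param graph An \code{igraph} graph.
#' @export
writeEdgeListTSV <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  colnames(el) <- if (igraph::is_directed(graph)) c("source", "target")
                  else c("node_a", "node_b")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
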