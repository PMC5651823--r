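#' Expression matrix with sample metadata
#'
#' Lightweight container for a gene-by-sample abundance table, in the spirit
#' of a \code{DGEList}: a numeric matrix plus a per-sample metadata frame and
#' a tag recording the abundance scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names are sample identifiers; both must be
#'   unique and non-empty.
#' @param samples data.frame with one row per column of \code{values}.
#'   Recognised columns: \code{sample}, \code{tissue}, \code{condition}
#'   (one of \code{"H"}, \code{"A"}, \code{"T"}), \code{source},
#'   \code{subject}, and optionally \code{distance}. Extra columns are kept.
#' @param scale one of \code{"counts"}, \code{"cpm"}, \code{"log2cpm"},
#'   \code{"abundance"}. On the counts scale all entries must be
#'   non-negative integers.
#'
#' @return An object of class \code{"ExpressionMatrix"}: a list with elements
#'   \code{values}, \code{samples} and \code{scale}.
#' @export
ExpressionMatrix <- function(values, samples, scale = "counts") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in 'values'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in 'values'")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(values))
    stop("'samples' must have one row per column of 'values'")
  if (is.null(samples$sample)) samples$sample <- colnames(values)
  if (!identical(as.character(samples$sample), colnames(values)))
    stop("'samples$sample' must match the column names of 'values'")
  if (!is.null(samples$condition)) {
    bad <- setdiff(unique(samples$condition), c("H", "A", "T"))
    if (length(bad))
      stop("unknown condition labels: ", paste(bad, collapse = ", "))
  }
  scale <- match.arg(scale, c("counts", "cpm", "log2cpm", "abundance"))
  if (scale == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts scale requires non-negative integer entries")
  }
  structure(list(values = values, samples = samples, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$samples$condition))
    print(table(tissue = x$samples$tissue, condition = x$samples$condition))
  invisible(x)
}

#' Subset an ExpressionMatrix
#'
#' @param x ExpressionMatrix.
#' @param genes character or logical or integer index of genes to keep.
#' @param samples index of samples to keep.
#' @return ExpressionMatrix restricted to the requested rows/columns.
#' @export
subset_em <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  s <- x$samples
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[match(colnames(v), s$sample), , drop = FALSE]
    rownames(s) <- NULL
  }
  ExpressionMatrix(v, s, x$scale)
}

#' Read a gene-by-sample TSV and its metadata into an ExpressionMatrix
#'
#' The matrix file is tab-separated with a header row; the first column holds
#' gene identifiers. The metadata file is tab-separated with columns
#' \code{sample}, \code{tissue}, \code{condition}, \code{source},
#' \code{subject} (additional columns are preserved).
#'
#' @param counts_file path to the matrix TSV.
#' @param metadata_file path to the metadata TSV.
#' @param scale abundance scale tag of the stored matrix.
#' @return ExpressionMatrix.
#' @export
read_expression_tsv <- function(counts_file, metadata_file, scale = "counts") {
  tab <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  meta <- utils::read.delim(metadata_file, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample))
    stop("metadata does not cover all samples in the matrix")
  rownames(meta) <- NULL
  ExpressionMatrix(m, meta, scale)
}

#' Write an ExpressionMatrix as TSV files
#'
#' @param x ExpressionMatrix.
#' @param counts_file output path for the gene-by-sample table (first column
#'   \code{gene}).
#' @param metadata_file optional output path for the sample metadata.
#' @return invisibly, \code{x}.
#' @export
write_expression_tsv <- function(x, counts_file, metadata_file = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_file))
    utils::write.table(x$samples, metadata_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' Used for housekeeping / negative-control gene lists. Blank lines and
#' lines starting with '#' are skipped.
#'
#' @param file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(file) {
  x <- readLines(file)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
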