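#' Expression matrix container
#'
#' A genes x samples matrix of expression values plus a declared measurement
#' scale. The scale is declared, never sniffed: GEO/ArrayExpress platforms mix
#' linear intensities and log2-transformed values, and silent auto-detection is
#' a reproducibility hazard. All fold-change arithmetic converts to linear
#' scale first; correlation and t-tests operate on the log2 scale.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene ids) and
#'   colnames (sample ids). Values must be finite; linear-scale values must be
#'   non-negative. At least 2 samples are required.
#' @param scale Either `"linear"` or `"log2"`.
#'
#' @return An object of class `expression_matrix` with elements `values` and
#'   `scale`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_matrix(m, "linear")
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (ncol(values) < 2) stop("at least 2 samples required", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be >= 0", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Expression values on a fixed scale
#'
#' `values_linear()` returns intensities on the linear scale (`2^x` for log2
#' input); `values_log2()` returns `log2(x + 1)` for linear input (the +1
#' offset keeps zero intensities finite) and the stored values for log2 input.
#'
#' @param x An `expression_matrix`.
#' @return A numeric matrix.
#' @export
values_linear <- function(x) {
  if (x$scale == "linear") x$values else 2^x$values
}

#' @rdname values_linear
#' @export
values_log2 <- function(x) {
  if (x$scale == "log2") x$values else log2(x$values + 1)
}

#' Subset an expression matrix
#'
#' @param x An `expression_matrix`.
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return An `expression_matrix`.
#' @export
subset_expression <- function(x, genes = gene_ids(x), samples = sample_ids(x)) {
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g) > 0) {
    stop("genes not in matrix: ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  }
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s) > 0) {
    stop("samples not in matrix: ", paste(utils::head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  expression_matrix(x$values[genes, samples, drop = FALSE], x$scale)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids. Duplicate
#' gene ids are collapsed by their mean (with a warning); duplicate sample ids
#' and non-numeric cells are errors naming the offending location. Missing
#' values are rejected.
#'
#' @param path Path to a tab-separated file.
#' @param scale Declared measurement scale, `"linear"` or `"log2"`.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 3) {
    stop("expression TSV needs a gene-id column and >= 2 sample columns",
         call. = FALSE)
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- df[[1]]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1]], genes[bad[1]], samples[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dups), " duplicated gene id(s) by mean: ",
            paste(utils::head(dups, 5), collapse = ", "), call. = FALSE)
    sums <- rowsum(vals, group = genes)  # rows ordered by sorted group
    counts <- as.vector(table(genes)[rownames(sums)])
    means <- sums / counts
    genes <- unique(genes)  # restore first-appearance order
    vals <- means[genes, , drop = FALSE]
  }
  rownames(vals) <- genes
  expression_matrix(vals, scale)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces doubles exactly.
#'
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  df <- data.frame(gene_id = gene_ids(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
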