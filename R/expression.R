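#' Categorize RPKM values
#'
#' Maps abundance values to the four bands used for expression heat maps:
#' below 0.1 RPKM \code{not_detected}, 0.1--0.5 \code{low} (both ends
#' closed), above 0.5 and below 60 \code{moderate}, and 60 RPKM or more
#' \code{high}. The bands partition [0, Inf); negative values are an error.
#'
#' @param x numeric vector of RPKM values.
#' @return character vector of category labels.
#' @examples
#' expressionCategory(c(0, 0.3, 5, 60))
#' @export
expressionCategory <- function(x) {
  if (any(is.na(x)) || any(x < 0)) stop("RPKM values must be >= 0")
  out <- rep("moderate", length(x))
  out[x < 0.1] <- "not_detected"
  out[x >= 0.1 & x <= 0.5] <- "low"
  out[x >= 60] <- "high"
  out
}

#' Tissue-specific expression calls
#'
#' A gene is called specific to tissue T when its value in T exceeds the
#' detection threshold and every other tissue is at or below it; otherwise
#' the call is \code{NA} (none). Invariant under tissue permutation up to
#' the label.
#'
#' @param mat numeric matrix, genes x tissues (>= 2 tissues), with dimnames.
#' @param detectThreshold RPKM detection threshold (default 0.5).
#' @return named character vector of tissue labels (NA = not specific).
#' @examples
#' m <- rbind(g1 = c(leaf = 0, flower = 70, fruit = 0.2))
#' tissueSpecific(m)
#' @export
tissueSpecific <- function(mat, detectThreshold = 0.5) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least two tissues")
  tiss <- colnames(mat)
  if (is.null(tiss)) tiss <- paste0("tissue", seq_len(ncol(mat)))
  out <- apply(mat, 1, function(v) {
    up <- which(v > detectThreshold)
    if (length(up) == 1L) tiss[up] else NA_character_
  })
  stats::setNames(as.character(out), rownames(mat))
}

#' Heatmap-ready transformed and row-ordered matrix
#'
#' Applies the log2(x + 1) transform (monotone within each row) and orders
#' rows by hierarchical clustering with average linkage on correlation
#' distance (1 - Pearson r). Rows are first sorted by identifier so that the
#' ordering is deterministic regardless of input order; rows with zero
#' variance get correlation distance 1 to everything (with a warning).
#'
#' @param mat numeric matrix, genes x tissues (>= 2 genes), RPKM.
#' @return a list: \code{matrix} (transformed, reordered), \code{row_order}
#'   (character vector of row ids in display order), \code{hclust} the
#'   clustering object.
#' @export
heatmapMatrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least two genes")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  lm <- log2(mat + 1)
  sds <- apply(lm, 1, stats::sd)
  if (any(sds == 0))
    warning("constant row(s): correlation distance set to 1 for ",
            paste(utils::head(rownames(lm)[sds == 0]), collapse = ", "))
  cc <- suppressWarnings(stats::cor(t(lm)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  ord <- rownames(lm)[hc$order]
  list(matrix = lm[ord, , drop = FALSE], row_order = ord, hclust = hc)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of tissue labels and gene identifiers in the first
#' column; values must be non-negative.
#'
#' @param path input TSV.
#' @return numeric matrix genes x tissues.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (any(is.na(m)) || any(m < 0)) stop("expression values must be >= 0")
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix genes x tissues.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
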