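#' Quantile-normalize arrays to a common intensity distribution
#'
#' Forces every column (array) of the matrix to share one empirical
#' distribution: the reference is the vector of row-wise means of the
#' column-sorted matrix, and each column's values are replaced by the
#' reference value at their within-column rank.  Ranks are preserved within
#' each column; ties receive the average of the tied reference values
#' (ties.method = "average").
#'
#' @param matrix numeric matrix without missing values, features x arrays.
#' @return matrix of the same shape; every column has the identical sorted
#'   value multiset.
#' @export
quantile_normalize <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) < 1L) stop("need at least one column")
  if (anyNA(matrix)) stop("missing values are not supported")
  if (ncol(matrix) == 1L) return(matrix)
  ref <- rowMeans(apply(matrix, 2L, sort, method = "radix"))
  out <- apply(matrix, 2L, function(col) {
    # distinct values get the reference value of their rank; a group of
    # tied values gets the mean of all reference values its group spans
    mapped <- ref[rank(col, ties.method = "first")]
    stats::ave(mapped, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Floor intensities at a positive epsilon
#'
#' Ratio and log transforms downstream require strictly positive values;
#' background-subtracted array intensities can be zero or negative.  Every
#' value below `epsilon` is replaced by `epsilon`; the number of floored
#' cells is attached as attribute `n_floored` and reported via message.
#'
#' @param matrix numeric matrix.
#' @param epsilon positive floor (default 1, raw Illumina-scale intensity).
#' @return floored matrix with attribute `n_floored`.
#' @export
floor_intensities <- function(matrix, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number")
  n <- sum(matrix < epsilon)
  if (n > 0) {
    matrix[matrix < epsilon] <- epsilon
    message(n, " intensit", if (n == 1) "y" else "ies",
            " floored at ", epsilon)
  }
  structure(matrix, n_floored = n)
}

#' Collapse probe-level rows to one row per gene
#'
#' Under the `max_mean_probe` strategy each gene is represented by its
#' probe with the highest mean intensity across all samples; ties are broken
#' by the lexicographically smaller probe id.  Probes without annotation are
#' dropped (count reported via message).
#'
#' @param matrix probe-level matrix with probe rownames.
#' @param annotation data.frame with columns `probe`, `gene`.
#' @param strategy collapse rule; only \dQuote{max_mean_probe}.
#' @return gene-level matrix with gene rownames and attribute
#'   `collapse_map` (data.frame gene, probe).
#' @export
collapse_probes <- function(matrix, annotation,
                            strategy = "max_mean_probe") {
  strategy <- match.arg(strategy, "max_mean_probe")
  annotation <- validate_annotation(annotation)
  if (nrow(annotation) == 0L) stop("empty annotation")
  keep <- rownames(matrix) %in% annotation$probe
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " unannotated probe(s) dropped")
  matrix <- matrix[keep, , drop = FALSE]
  if (nrow(matrix) == 0L) stop("no annotated probes left")
  gene <- annotation$gene[match(rownames(matrix), annotation$probe)]
  means <- rowMeans(matrix)
  ord <- order(gene, -means, rownames(matrix), method = "radix")
  first <- ord[!duplicated(gene[ord])]
  out <- matrix[first, , drop = FALSE]
  map <- data.frame(gene = gene[first], probe = rownames(matrix)[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- gene[first]
  out <- out[order(rownames(out)), , drop = FALSE]
  structure(out, collapse_map = map[order(map$gene), ])
}

#' Log2-transform and mean-center a series (display transform)
#'
#' The transform used for trajectory figures: per feature,
#' `log2(x_t) - mean_t(log2(x_t))`, so each row sums to zero and
#' multiplicative scaling of a series cancels.
#'
#' @param series positive numeric vector, or matrix with features as rows.
#' @return transformed vector/matrix; each feature sums to 0.
#' @export
log2_mean_center <- function(series) {
  if (any(series <= 0))
    stop("non-positive values: floor intensities before the log transform")
  lg <- log2(series)
  if (is.matrix(lg)) lg - rowMeans(lg) else lg - mean(lg)
}
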