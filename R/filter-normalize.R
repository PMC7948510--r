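#' Filter genes expressed above background
#'
#' Retains a gene only if its median count across samples strictly exceeds
#' the overall median signal of the matrix. The overall median is by default
#' the median of all matrix entries; `overall = "gene_medians"` instead uses
#' the median of the per-gene medians (both readings of "overall median
#' signal" occur in practice; the default is the literal one).
#'
#' @param counts gene-by-sample numeric matrix (at least 2 samples).
#' @param overall how the overall median is computed: `"entries"` (default)
#'   or `"gene_medians"`.
#' @return The filtered count matrix. If nothing passes, a 0-row matrix with
#'   a warning.
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(5, 5), c = c(10, 10))
#' filter_background(m)   # keeps only gene c
filter_background <- function(counts, overall = c("entries", "gene_medians")) {
  overall <- match.arg(overall)
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  gene_med <- apply(counts, 1, stats::median)
  cutoff <- switch(overall,
                   entries = stats::median(counts),
                   gene_medians = stats::median(gene_med))
  keep <- gene_med > cutoff
  if (!any(keep))
    warning("no gene passes the background filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for sequencing depth: the reference for
#' each gene is the geometric mean of its counts across samples, computed
#' over genes with non-zero counts in every sample; each sample's factor is
#' the median across those genes of the ratio of its count to the reference.
#'
#' @param counts gene-by-sample numeric matrix of non-negative counts.
#' @return A named numeric vector of positive per-sample factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m)  # c(1/sqrt(2), sqrt(2)): second library is twice as deep
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has non-zero counts in every sample; cannot estimate size factors")
  x <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(x)))
  sf <- apply(x / ref, 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts and stabilize variance
#'
#' Divides each sample by its size factor and applies the shifted-log
#' transform `log2(count / sf + 1)`, a monotone variance-stabilizing
#' transform of the normalized counts.
#'
#' @param counts gene-by-sample numeric matrix.
#' @param sf per-sample size factors; estimated with [size_factors()] if
#'   omitted.
#' @return An object of class `"norm_matrix"`: a list with `values`
#'   (log2-scale matrix), `norm_counts` (counts / size factor, linear
#'   scale) and `size_factors`.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  norm <- sweep(counts, 2, sf, "/")
  structure(list(values = log2(norm + 1),
                 norm_counts = norm,
                 size_factors = sf),
            class = "norm_matrix")
}

# Pull the log-scale expression matrix out of a norm_matrix or pass a bare
# matrix through.
norm_values <- function(x) {
  if (inherits(x, "norm_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a norm_matrix or a numeric matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d samples, size factors in [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}
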