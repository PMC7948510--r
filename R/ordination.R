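#' Principal component analysis of expression profiles
#'
#' PCA of samples in gene space: genes are centered (not scaled) and the
#' samples' coordinates on the orthogonal components are returned together
#' with the fraction of variance each component explains. The sign of each
#' component is fixed by making its largest-magnitude gene loading positive,
#' so results are reproducible across platforms.
#'
#' @param x a `"norm_matrix"` from [normalize_counts()] or a gene-by-sample
#'   numeric matrix of expression values.
#' @return A list of class `"expression_pca"` with `scores` (samples x
#'   components), `loadings` (genes x components) and `var_explained`
#'   (fractions summing to 1 over the full rank).
#' @export
expression_pca <- function(x) {
  v <- norm_values(x)
  stopifnot(ncol(v) >= 2)
  centered <- v - rowMeans(v)
  if (sum(centered^2) == 0)
    stop("expression matrix is constant across samples; PCA undefined")
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "expression_pca")
}

#' Spearman correlation of average expression between cell types
#'
#' Averages expression over the samples of each cell type and computes the
#' Spearman rank correlation between every pair of type-average profiles.
#' Ties are mid-ranked; two-sided p-values use the large-sample t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom, where n is the number of genes.
#'
#' @param x a `"norm_matrix"` or gene-by-sample expression matrix (at least
#'   3 genes).
#' @param type_map named character vector mapping sample id to cell type
#'   (or, unnamed, in column order).
#' @return A list of class `"spearman_types"` with `rho` and `p_value`
#'   matrices (types x types), `avg` (gene x type mean expression) and
#'   `n_genes`. A type whose average profile is constant has undefined rank
#'   correlation and yields `NaN` with a warning.
#' @export
spearman_between_types <- function(x, type_map) {
  v <- norm_values(x)
  stopifnot(nrow(v) >= 3)
  if (is.null(names(type_map))) {
    stopifnot(length(type_map) == ncol(v))
    names(type_map) <- colnames(v)
  }
  if (!all(colnames(v) %in% names(type_map)))
    stop("type_map is missing samples: ",
         paste(setdiff(colnames(v), names(type_map)), collapse = ", "))
  types <- unique(unname(type_map[colnames(v)]))
  avg <- vapply(types, function(ty) {
    rowMeans(v[, type_map[colnames(v)] == ty, drop = FALSE])
  }, numeric(nrow(v)))
  colnames(avg) <- types

  const <- apply(avg, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    warning("constant average profile(s): ",
            paste(types[const], collapse = ", "),
            "; Spearman rho undefined (NaN)")
  rho <- suppressWarnings(stats::cor(avg, method = "spearman"))
  rho[const, ] <- NaN
  rho[, const] <- NaN
  diag(rho)[!const] <- 1

  n <- nrow(avg)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(rho = rho, p_value = p, avg = avg, n_genes = n),
            class = "spearman_types")
}

#' Hierarchical clustering of samples on rank-correlation distance
#'
#' Agglomerative clustering of samples with distance `1 - Spearman rho`
#' between expression profiles and average linkage, emitting the dendrogram
#' both as an `hclust` object and as Newick text. A precomputed `dist`
#' object may be supplied instead of an expression matrix.
#'
#' @param x a `"norm_matrix"`, a gene-by-sample expression matrix, or a
#'   `dist` object of pairwise sample distances.
#' @param method agglomeration method passed to [stats::hclust()].
#' @return A list of class `"sample_dendrogram"` with `hclust`, `newick`
#'   (string), and `dist`.
#' @export
cluster_samples <- function(x, method = "average") {
  d <- if (inherits(x, "dist")) {
    x
  } else {
    v <- norm_values(x)
    stats::as.dist(1 - stats::cor(v, method = "spearman"))
  }
  hc <- stats::hclust(d, method = method)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = newick, dist = d),
            class = "sample_dendrogram")
}

#' @export
print.expression_pca <- function(x, ...) {
  ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 1)
  cat(sprintf("expression_pca: %d samples, variance explained: %s%%\n",
              nrow(x$scores), paste(ve, collapse = ", ")))
  invisible(x)
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat("sample_dendrogram (", x$hclust$method, " linkage):\n  ",
      x$newick, "\n", sep = "")
  invisible(x)
}
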