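#' Simulate a negative-binomial count matrix with planted differential genes
#'
#' Draws a gene-by-sample matrix of sequencing-style counts under the
#' standard negative-binomial model for bulk RNA-seq: the count for gene g in
#' sample s has mean `sf_s * mu_g * 2^(lfc_g)` (the log2 fold change applies
#' in the second group only) and variance `mu + dispersion * mu^2`. A chosen
#' number of genes is planted as differentially expressed at `+log2fc` or
#' `-log2fc` (sign drawn at random per gene); all other genes have log2 fold
#' change 0. Per-sample size factors model library-size differences.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (two groups; at least 2 each,
#'   mirroring experiments with several biological replicates per condition).
#' @param n_de number of planted differentially expressed genes.
#' @param log2fc absolute planted log2 fold change for DE genes.
#' @param dispersion common negative-binomial dispersion (must be > 0);
#'   variance is `mu + dispersion * mu^2`, so small values approach Poisson.
#' @param size_factors optional vector of per-sample positive scalings
#'   (length `2 * n_per_group`); by default drawn log-normally around 1.
#' @param baseline_means optional vector of per-gene positive baseline means;
#'   by default drawn log-normally (median 200, sdlog 1).
#' @param group_names labels for the two groups.
#' @param seed integer seed; identical inputs give identical matrices.
#'
#' @return An object of class `"sim_counts"`: a list with `counts` (integer
#'   matrix, genes x samples, dimnames set), `groups` (named character vector
#'   mapping sample id to group), and `truth` (a list with `size_factors`,
#'   `de_gene_ids`, `log2fc` per gene, `dispersion`, `baseline_means`,
#'   `seed`).
#' @export
#' @examples
#' sim <- simulate_count_matrix(n_genes = 50, n_per_group = 3, n_de = 5,
#'                              seed = 1)
#' dim(sim$counts)
simulate_count_matrix <- function(n_genes = 2000, n_per_group = 4,
                                  n_de = 100, log2fc = 2,
                                  dispersion = 0.05,
                                  size_factors = NULL,
                                  baseline_means = NULL,
                                  group_names = c("A", "B"),
                                  seed = 1) {
  stopifnot(n_genes >= 1, n_per_group >= 2, n_de >= 0, n_de <= n_genes,
            length(group_names) == 2)
  if (dispersion <= 0) stop("dispersion must be positive")
  n_samples <- 2L * n_per_group
  if (!is.null(baseline_means) && any(baseline_means <= 0))
    stop("baseline means must be positive")
  if (!is.null(size_factors)) {
    if (length(size_factors) != n_samples || any(size_factors <= 0))
      stop("size_factors must be ", n_samples, " positive values")
  }

  withr::with_seed(seed, {
    if (is.null(baseline_means))
      baseline_means <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
    if (is.null(size_factors))
      size_factors <- stats::rlnorm(n_samples, meanlog = 0, sdlog = 0.3)

    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    sample_ids <- paste0(rep(group_names, each = n_per_group),
                         rep(seq_len(n_per_group), times = 2))
    groups <- stats::setNames(rep(group_names, each = n_per_group),
                              sample_ids)

    lfc <- numeric(n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    if (n_de > 0)
      lfc[de_idx] <- log2fc * sample(c(-1, 1), n_de, replace = TRUE)

    in_b <- groups == group_names[2]
    mu <- outer(baseline_means, size_factors) *
      2^outer(lfc, as.numeric(in_b))
    counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                    size = 1 / dispersion),
                     nrow = n_genes,
                     dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"

    truth <- list(size_factors = stats::setNames(size_factors, sample_ids),
                  de_gene_ids = gene_ids[de_idx],
                  log2fc = stats::setNames(lfc, gene_ids),
                  dispersion = dispersion,
                  baseline_means = stats::setNames(baseline_means, gene_ids),
                  group_labels = groups,
                  seed = as.integer(seed))
    structure(list(counts = counts, groups = groups, truth = truth),
              class = "sim_counts")
  })
}

#' Build a gene-set collection with one planted enriched set
#'
#' Constructs `n_sets` gene sets over a gene universe. One designated set
#' (named `"planted_set"`) contains a chosen number of genes from a supplied
#' differential list, topped up with non-differential genes; the remaining
#' decoy sets are drawn uniformly from the universe. Used to test that
#' enrichment analysis finds a truly enriched set while leaving random sets
#' non-significant.
#'
#' @param universe character vector of all gene ids.
#' @param de_genes character vector of differential gene ids (subset of
#'   `universe`).
#' @param n_sets total number of sets, including the planted one.
#' @param set_size genes per set.
#' @param planted_overlap how many members of the planted set come from
#'   `de_genes` (0..`set_size`).
#' @param seed integer seed.
#' @return A list of class `"gene_set_collection"` with `sets` (named list of
#'   character vectors; first element `planted_set`) and `universe`.
#' @seealso [fisher_enrichment()], [write_gmt()]
#' @export
simulate_gene_sets <- function(universe, de_genes, n_sets = 50,
                               set_size = 50, planted_overlap = 40,
                               seed = 1) {
  stopifnot(planted_overlap >= 0, planted_overlap <= set_size,
            set_size <= length(universe))
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  if (planted_overlap > length(de_genes))
    stop("planted_overlap exceeds the number of differential genes")
  withr::with_seed(seed, {
    non_de <- setdiff(universe, de_genes)
    planted <- c(if (planted_overlap > 0)
                   sample(de_genes, planted_overlap),
                 if (set_size - planted_overlap > 0)
                   sample(non_de, set_size - planted_overlap))
    decoys <- lapply(seq_len(n_sets - 1),
                     function(i) sample(universe, set_size))
    sets <- c(list(planted), decoys)
    names(sets) <- c("planted_set",
                     sprintf("decoy_set_%03d", seq_len(n_sets - 1)))
    structure(list(sets = sets, universe = universe),
              class = "gene_set_collection")
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf(
    "sim_counts: %d genes x %d samples, %d planted DE genes, dispersion %g, seed %d\n",
    nrow(x$counts), ncol(x$counts), length(x$truth$de_gene_ids),
    x$truth$dispersion, x$truth$seed))
  invisible(x)
}
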