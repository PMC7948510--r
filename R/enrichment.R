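#' Right-tailed hypergeometric (Fisher's exact) enrichment p-value
#'
#' Probability of drawing at least `k` genes of a `K`-gene set when `n`
#' genes are drawn without replacement from a universe of `N`, i.e. the
#' right tail of the hypergeometric distribution. This is the one-sided
#' Fisher's exact test for over-representation on the 2x2 table
#' (in list / not in list) x (in set / not in set).
#'
#' @param k observed overlap between gene list and set.
#' @param K set size within the universe.
#' @param n gene-list size.
#' @param N universe size.
#' @return The right-tail p-value `P(X >= k)`; vectorized over arguments.
#' @export
#' @examples
#' hyper_test_right(4, K = 5, n = 4, N = 20)  # 5 / choose(20, 4)
hyper_test_right <- function(k, K, n, N) {
  stopifnot(all(k >= 0), all(K <= N), all(n <= N), all(k <= pmin(K, n)))
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set enrichment by the right-tailed Fisher's exact test
#'
#' Tests each gene set for over-representation of a gene list within a gene
#' universe. Set members outside the universe are ignored; list genes
#' outside the universe are dropped with a warning. A set is called
#' significant when its enrichment p-value is below `alpha`.
#'
#' @param gene_list character vector of genes of interest (e.g. one
#'   direction of a differential-expression result).
#' @param universe character vector of all queryable genes (e.g. all genes
#'   that passed the background filter).
#' @param sets a `"gene_set_collection"`, a named list of character
#'   vectors, or a GMT path readable by [read_gmt()].
#' @param alpha significance cutoff on the enrichment p-value.
#' @param direction optional label (`"up"`/`"down"`) recorded in the
#'   result, for bookkeeping when the two directions are tested separately.
#' @return A data frame, one row per set: `set_name`, `k_overlap`,
#'   `n_list`, `K_set`, `N_universe`, `p_value`, `significant`,
#'   `direction`, ordered by increasing p-value.
#' @export
fisher_enrichment <- function(gene_list, universe, sets, alpha = 0.01,
                              direction = NA_character_) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (is.character(sets) && length(sets) == 1 && file.exists(sets))
    sets <- read_gmt(sets)
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0) {
    warning(length(outside), " gene(s) in the list are not in the universe ",
            "and were dropped")
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe)
  n <- length(gene_list)
  K <- vapply(sets, function(s) length(intersect(unique(s), universe)),
              integer(1))
  k <- vapply(sets, function(s) length(intersect(unique(s), gene_list)),
              integer(1))
  p <- hyper_test_right(k, K, n, N)
  out <- data.frame(set_name = names(sets), k_overlap = k, n_list = n,
                    K_set = K, N_universe = N, p_value = p,
                    significant = p < alpha, direction = direction,
                    row.names = NULL)
  out[order(out$p_value), , drop = FALSE]
}

#' Enrichment of up- and down-regulated genes, evaluated separately
#'
#' Convenience wrapper running [fisher_enrichment()] once on the
#' up-regulated and once on the down-regulated gene list of a
#' differential-expression result.
#'
#' @param de a `"de_result"` from [differential_expression()].
#' @param universe gene universe (defaults to all genes in `de`).
#' @param sets gene sets as in [fisher_enrichment()].
#' @param alpha significance cutoff.
#' @return A list with data frames `up` and `down`.
#' @export
enrich_by_direction <- function(de, sets, universe = de$gene_id,
                                alpha = 0.01) {
  lists <- split_by_direction(de)
  list(up = fisher_enrichment(lists$up, universe, sets, alpha, "up"),
       down = fisher_enrichment(lists$down, universe, sets, alpha, "down"))
}
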