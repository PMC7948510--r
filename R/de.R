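#' Differential expression between two groups by ANOVA and fold change
#'
#' Per-gene two-group comparison of normalized expression: a one-way ANOVA
#' on the log-scale values (for two groups this is exactly the
#' pooled-variance two-sample t test), Benjamini-Hochberg FDR correction,
#' and a fold-change filter. A gene is selected when its q-value is below
#' `alpha` and the magnitude of its fold change is at least `fc_threshold`.
#'
#' Fold change is the ratio of group-average normalized counts (linear
#' scale by default; `fold_on = "log"` uses the ratio of average log-scale
#' values instead) and is reported in signed-symmetric form for the first
#' group relative to the second: a gene 2-fold higher in `group_a` has
#' fold change `+2` (direction `"up"`), a gene 2-fold lower has `-2`
#' (direction `"down"`), so the cutoff reads symmetrically as
#' `|fold change| >= fc_threshold`.
#'
#' Genes with zero pooled within-group variance are degenerate for the
#' ANOVA; they get `p = 0` when the group means differ and `p = 1`
#' otherwise, with a warning.
#'
#' @param counts gene-by-sample count matrix, or a `"norm_matrix"` from
#'   [normalize_counts()] (counts are normalized internally when a raw
#'   matrix is given).
#' @param groups named character vector mapping sample id to group (or in
#'   column order when unnamed).
#' @param group_a,group_b the two group labels to compare (each with at
#'   least 2 samples).
#' @param alpha q-value cutoff for selection.
#' @param fc_threshold fold-change magnitude cutoff for selection.
#' @param fold_on compute the fold change on `"counts"` (group means of
#'   normalized counts, default) or `"log"` (group means of log-scale
#'   values).
#' @param q_method `"BH"` (Benjamini-Hochberg step-up, default) or
#'   `"storey"` (Storey's q-value with the fixed-lambda 0.5 pi0 estimate).
#' @return A data frame of class `"de_result"`, one row per gene:
#'   `gene_id`, `mean_a`, `mean_b` (average log-scale expression),
#'   `fold_change`, `p_value`, `q_value`, `selected`, `direction`
#'   (`"up"` = higher in `group_a`).
#' @export
#' @examples
#' sim <- simulate_count_matrix(n_genes = 200, n_de = 20, seed = 1)
#' de <- differential_expression(sim$counts, sim$groups, "A", "B")
#' table(de$selected, de$direction)
differential_expression <- function(counts, groups, group_a, group_b,
                                    alpha = 0.05, fc_threshold = 1.5,
                                    fold_on = c("counts", "log"),
                                    q_method = c("BH", "storey")) {
  fold_on <- match.arg(fold_on)
  q_method <- match.arg(q_method)
  nm <- if (inherits(counts, "norm_matrix")) counts else normalize_counts(counts)
  v <- nm$values
  if (is.null(names(groups))) {
    stopifnot(length(groups) == ncol(v))
    names(groups) <- colnames(v)
  }
  ia <- which(groups[colnames(v)] == group_a)
  ib <- which(groups[colnames(v)] == group_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 samples")

  va <- v[, ia, drop = FALSE]; vb <- v[, ib, drop = FALSE]
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  ss_a <- rowSums((va - mean_a)^2)
  ss_b <- rowSums((vb - mean_b)^2)
  sp2 <- (ss_a + ss_b) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))

  tstat <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  degen <- sp2 == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero within-group variance; ",
            "p set to 0 (means differ) or 1 (means equal)")
    p[degen] <- ifelse(mean_a[degen] == mean_b[degen], 1, 0)
  }
  q <- switch(q_method,
              BH = stats::p.adjust(p, method = "BH"),
              storey = storey_qvalue(p))

  base <- switch(fold_on,
                 counts = nm$norm_counts,
                 log = v)
  ba <- rowMeans(base[, ia, drop = FALSE])
  bb <- rowMeans(base[, ib, drop = FALSE])
  r <- ba / bb
  fold <- ifelse(r >= 1, r, -1 / r)
  fold[ba == 0 & bb == 0] <- 1   # absent in both groups: no change
  direction <- ifelse(ba > bb, "up", "down")
  direction[ba == bb] <- NA_character_

  selected <- q < alpha & abs(fold) >= fc_threshold
  selected[is.na(selected)] <- FALSE

  structure(data.frame(gene_id = rownames(v), mean_a = mean_a,
                       mean_b = mean_b, fold_change = fold,
                       p_value = p, q_value = q, selected = selected,
                       direction = direction, row.names = NULL),
            class = c("de_result", "data.frame"))
}

# Storey's q-value with pi0 estimated at lambda = 0.5.
storey_qvalue <- function(p) {
  m <- length(p)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(1, cummin(q))
  q[order(o)]
}

#' Split selected genes by direction of change
#'
#' Partitions the selected genes of a [differential_expression()] result
#' into the up-regulated and down-regulated lists, so each direction can be
#' tested for enrichment separately.
#'
#' @param de a `"de_result"` data frame.
#' @return A list with character vectors `up` and `down` (gene ids).
#' @export
split_by_direction <- function(de) {
  sel <- de[de$selected, , drop = FALSE]
  list(up = sel$gene_id[sel$direction == "up"],
       down = sel$gene_id[sel$direction == "down"])
}
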