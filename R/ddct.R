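#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' For each sample, the target gene's Ct is referenced to the housekeeping
#' gene (`dCt = ct_target - ct_reference`). For each (target, group), the
#' group-mean dCt is referenced to the control group
#' (`ddCt = mean dCt(group) - mean dCt(control)`) and the expression fold
#' change relative to the control group is `2^(-ddCt)`. A per-target
#' one-way ANOVA across groups on the per-sample dCt values gives an
#' overall p-value for group differences.
#'
#' @param ct data frame with columns `sample`, `group`, `target_gene`,
#'   `reference_gene`, `ct_target`, `ct_reference` (Ct values in cycles,
#'   positive).
#' @param control_group the group every other group is expressed relative
#'   to.
#' @return A data frame, one row per (target_gene, group): `target_gene`,
#'   `group`, `n`, `delta_ct_mean`, `delta_delta_ct`, `fold_change`,
#'   `p_anova` (NA when fewer than two groups or no residual degrees of
#'   freedom). The control group appears with fold change 1.
#' @export
#' @examples
#' ct <- data.frame(sample = c("t1", "t2", "c1", "c2"),
#'                  group = c("treated", "treated", "control", "control"),
#'                  target_gene = "CDX2", reference_gene = "GAPDH",
#'                  ct_target = c(20, 20, 24, 24), ct_reference = 18)
#' delta_delta_ct(ct, "control")   # treated fold change 16
delta_delta_ct <- function(ct, control_group) {
  needed <- c("sample", "group", "target_gene", "reference_gene",
              "ct_target", "ct_reference")
  missing_cols <- setdiff(needed, names(ct))
  if (length(missing_cols) > 0)
    stop("ct table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- !is.finite(ct$ct_reference) | ct$ct_reference <= 0
  if (any(bad))
    stop("missing/invalid reference-gene Ct for sample(s): ",
         paste(unique(ct$sample[bad]), collapse = ", "))
  if (!control_group %in% ct$group)
    stop("control group '", control_group, "' not present in the table")

  ct$dct <- ct$ct_target - ct$ct_reference
  out <- do.call(rbind, lapply(split(ct, ct$target_gene), function(d) {
    grp_mean <- tapply(d$dct, d$group, mean)
    if (!control_group %in% names(grp_mean))
      stop("target '", d$target_gene[1], "' has no rows in the control group")
    ddct <- grp_mean - grp_mean[[control_group]]
    p <- NA_real_
    if (length(grp_mean) >= 2 && nrow(d) > length(grp_mean)) {
      fit <- stats::aov(dct ~ group, data = d)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    data.frame(target_gene = d$target_gene[1],
               group = names(grp_mean),
               n = as.integer(table(d$group)[names(grp_mean)]),
               delta_ct_mean = as.numeric(grp_mean),
               delta_delta_ct = as.numeric(ddct),
               fold_change = 2^(-as.numeric(ddct)),
               p_anova = p,
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
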