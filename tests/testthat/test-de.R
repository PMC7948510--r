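test_that("identical groups produce unit fold changes and no selections", {
  m <- matrix(rep(c(10, 50, 200), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  suppressWarnings(de <- differential_expression(m, groups, "A", "B"))
  expect_equal(de$fold_change, rep(1, 3))
  expect_false(any(de$selected))
})

test_that("q-values follow the Benjamini-Hochberg step-up procedure", {
  # hand-evaluated example: (0.01, 0.02, 0.03) with m = 3 all adjust to 0.03
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
  # the package's DE q-values are the BH adjustment of its p-values
  sim <- simulate_count_matrix(n_genes = 120, n_per_group = 3, n_de = 12,
                               seed = 13)
  de <- differential_expression(sim$counts, sim$groups, "A", "B")
  expect_equal(de$q_value, bh_oracle(de$p_value), tolerance = 1e-12)
  qs <- de$q_value[order(de$p_value)]
  expect_true(all(diff(qs) >= -1e-15))
})

test_that("q-values are invariant to gene order", {
  sim <- simulate_count_matrix(n_genes = 80, n_per_group = 3, n_de = 8,
                               seed = 14)
  de1 <- differential_expression(sim$counts, sim$groups, "A", "B")
  perm <- sample(nrow(sim$counts))
  de2 <- differential_expression(sim$counts[perm, ], sim$groups, "A", "B")
  expect_equal(de2$q_value[match(de1$gene_id, de2$gene_id)], de1$q_value)
})

test_that("the ANOVA p-value equals the pooled two-sample t-test", {
  sim <- simulate_count_matrix(n_genes = 40, n_per_group = 4, n_de = 4,
                               seed = 15)
  de <- differential_expression(sim$counts, sim$groups, "A", "B")
  v <- normalize_counts(sim$counts)$values
  grp <- factor(sim$groups[colnames(v)])
  for (g in sample(rownames(v), 8)) {
    p_aov <- anova(lm(v[g, ] ~ grp))[["Pr(>F)"]][1]
    expect_equal(de$p_value[de$gene_id == g], p_aov, tolerance = 1e-10)
  }
})

test_that("selection is exactly q < 0.05 AND |fold| >= 1.5", {
  for (seed in 16:18) {
    sim <- simulate_count_matrix(n_genes = 300, n_per_group = 4, n_de = 60,
                                 log2fc = 1, seed = seed)
    de <- differential_expression(sim$counts, sim$groups, "A", "B")
    expect_equal(de$selected,
                 de$q_value < 0.05 & abs(de$fold_change) >= 1.5)
    expect_true(all(abs(de$fold_change) >= 1, na.rm = TRUE))
  }
})

test_that("fold changes are signed-symmetric and direction-consistent", {
  m <- rbind(up4 = c(400, 400, 100, 100),
             down4 = c(100, 100, 400, 400),
             flat = c(100, 100, 100, 100))
  colnames(m) <- paste0("s", 1:4)
  groups <- setNames(c("A", "A", "B", "B"), colnames(m))
  suppressWarnings(de <- differential_expression(m, groups, "A", "B",
                                                 fold_on = "counts"))
  expect_equal(de$fold_change[de$gene_id == "up4"], 4)
  expect_equal(de$direction[de$gene_id == "up4"], "up")
  expect_equal(de$fold_change[de$gene_id == "down4"], -4)
  expect_equal(de$direction[de$gene_id == "down4"], "down")
  expect_equal(de$fold_change[de$gene_id == "flat"], 1)
  expect_true(is.na(de$direction[de$gene_id == "flat"]))
})

test_that("zero within-group variance triggers the degenerate p rule", {
  m <- rbind(gdiff = c(8, 8, 16, 16), gsame = c(8, 8, 8, 8))
  colnames(m) <- paste0("s", 1:4)
  groups <- setNames(c("A", "A", "B", "B"), colnames(m))
  nm <- normalize_counts(m, sf = setNames(rep(1, 4), colnames(m)))
  expect_warning(de <- differential_expression(nm, groups, "A", "B"),
                 "zero within-group variance")
  expect_equal(de$p_value[de$gene_id == "gdiff"], 0)
  expect_equal(de$p_value[de$gene_id == "gsame"], 1)
})

test_that("direction split partitions exactly the selected genes", {
  sim <- simulate_count_matrix(n_genes = 400, n_per_group = 4, n_de = 80,
                               seed = 19)
  de <- differential_expression(sim$counts, sim$groups, "A", "B")
  lists <- split_by_direction(de)
  sel <- de[de$selected, ]
  expect_setequal(c(lists$up, lists$down), sel$gene_id)
  expect_length(intersect(lists$up, lists$down), 0)
  expect_setequal(lists$up, sel$gene_id[sel$fold_change > 0])
  expect_setequal(lists$down, sel$gene_id[sel$fold_change < 0])

  none <- de[de$q_value > 2, ]   # empty frame
  empty <- split_by_direction(none)
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("planted differential genes are recovered with controlled FDP", {
  sim <- simulate_count_matrix(n_genes = 1000, n_per_group = 4, n_de = 100,
                               log2fc = 2, dispersion = 0.05, seed = 20)
  de <- differential_expression(sim$counts, sim$groups, "A", "B")
  sel <- de$gene_id[de$selected]
  power <- mean(sim$truth$de_gene_ids %in% sel)
  fdp <- if (length(sel) > 0) mean(!(sel %in% sim$truth$de_gene_ids)) else 0
  expect_gt(power, 0.8)
  expect_lt(fdp, 0.10)
  # planted direction agrees with the reported sign (group B carries the
  # planted shift, so positive planted log2fc means higher in B = "down"
  # for the A-relative fold change)
  planted_up_in_b <- names(sim$truth$log2fc)[sim$truth$log2fc > 0]
  hit <- intersect(planted_up_in_b, sel)
  expect_true(all(de$direction[match(hit, de$gene_id)] == "down"))
})

test_that("Storey q-values are a valid monotone alternative", {
  sim <- simulate_count_matrix(n_genes = 200, n_per_group = 3, n_de = 30,
                               seed = 22)
  de_bh <- differential_expression(sim$counts, sim$groups, "A", "B")
  de_st <- differential_expression(sim$counts, sim$groups, "A", "B",
                                   q_method = "storey")
  expect_equal(de_st$p_value, de_bh$p_value)
  expect_true(all(de_st$q_value <= de_bh$q_value + 1e-12))
  o <- order(de_st$p_value)
  expect_true(all(diff(de_st$q_value[o]) >= -1e-15))
})
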