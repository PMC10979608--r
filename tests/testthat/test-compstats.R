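norm_pair <- function(seed = 1, stress_fold = 1, ...) {
  pair <- small_count_pair(seed = seed, stress_fold = stress_fold, ...)
  list(spec = pair$spec, nm = normalize_log(filter_genes(pair$cm, 1)))
}

test_that("pseudo-bulk profiles are per-gene means over the subset", {
  m <- rbind(g1 = c(1, 3), g2 = c(0, 2))
  colnames(m) <- c("c1", "c2")
  nm <- count_matrix(Matrix::Matrix(m, sparse = TRUE))
  expect_equal(unname(pseudobulk_profile(nm, "c1")), c(1, 0))  # single cell
  expect_equal(unname(pseudobulk_profile(nm, c("c1", "c2"))), c(2, 1))
  expect_error(pseudobulk_profile(nm, character()), "empty")
})

test_that("pseudo-bulk correlation applies the size rules and strong flag", {
  p <- norm_pair(seed = 2)
  labs <- p$nm$cell_meta$protocol
  # identical cell sets on both sides: r^2 exactly 1
  nm2 <- p$nm
  nm2$cell_meta$protocol <- rep(c("A", "B"), length.out = ncol(nm2$counts))
  dup <- scpbench:::subset_cm(p$nm, j = rep(seq_len(40), 2))
  dup$cell_meta$protocol <- rep(c("X", "Y"), each = 40)
  dup$cell_meta$barcode <- paste0(dup$cell_meta$barcode, seq_len(80))
  colnames(dup$counts) <- dup$cell_meta$barcode
  res <- pseudobulk_correlation(dup, downsample = FALSE)
  expect_equal(res$r_squared[res$scope == "global"], 1)
  expect_true(res$passed_strong[res$scope == "global"])

  # a type under the 100-cell rule is skipped with the reason recorded
  types <- p$nm$cell_meta$cell_type          # 2 types x 40 cells/protocol = 80 < 100
  res2 <- pseudobulk_correlation(p$nm, cell_type_labels = types, seed = 1)
  expect_true(all(res2$skipped[res2$scope != "global"]))
  expect_true(all(res2$reason[res2$scope != "global"] == "min_total"))

  # per-condition rule: 30 vs 110 cells of one type fails min_per_cond = 20?
  # no - 30 > 20; shrink to 15 to trigger it
  labs3 <- c(rep("A", 15), rep("B", 110))
  ct3 <- rep("t1", 125)
  sub <- scpbench:::subset_cm(p$nm, j = seq_len(125))
  sub$cell_meta$protocol <- labs3
  res3 <- pseudobulk_correlation(sub, protocol_labels = labs3,
                                 cell_type_labels = ct3, seed = 1)
  expect_equal(res3$reason[res3$scope == "t1"], "min_per_cond")

  # downsampling equalizes the profiled cell numbers
  res4 <- pseudobulk_correlation(sub, protocol_labels = labs3, seed = 1)
  expect_equal(res4$n_a[1], res4$n_b[1])
  expect_error(pseudobulk_correlation(p$nm, protocol_labels = rep("A", ncol(p$nm$counts))),
               "two protocols")
})

test_that("null simulated pairs give near-perfect global correlation", {
  r2 <- vapply(1:5, function(s) {
    spec <- synthetic_spec(n_cell_types = 2, cells_per_type_per_protocol = 100,
                           n_genes = 300, library_size_log_mean = log(500),
                           seed = 30 + s)
    nm <- normalize_log(filter_genes(simulate_count_pair(spec), 1))
    pseudobulk_correlation(nm, seed = s)$r_squared[1]
  }, numeric(1))
  expect_true(all(r2 > 0.95))
})

test_that("composition comparison is descriptive, bootstrapped and symmetric", {
  ct <- c(rep("t1", 60), rep("t2", 40), rep("t1", 60), rep("t2", 40))
  pr <- rep(c("A", "B"), each = 100)
  res <- composition_compare(ct, pr, n_boot = 200, seed = 1)
  expect_equal(res$log2_ratio, c(0, 0))                  # identical composition
  expect_equal(sum(res$prop_a), 1)
  expect_equal(sum(res$prop_b), 1)

  # type in A only: pseudo-count keeps the ratio finite, CI excludes 0
  ct2 <- c(rep("t1", 90), rep("t2", 10), rep("t1", 100))
  res2 <- composition_compare(ct2, pr, n_boot = 400, seed = 2)
  row <- res2[res2$cell_type == "t2", ]
  expect_true(is.finite(row$log2_ratio))
  expect_gt(row$ci_low, 0)

  # swapping protocols negates the ratios
  res3 <- composition_compare(ct2, ifelse(pr == "A", "B", "A"), n_boot = 10, seed = 3)
  expect_equal(res3$log2_ratio, -res2$log2_ratio)
})

test_that("differential expression applies fold, FDR and presence filters", {
  p <- norm_pair(seed = 4)
  # identical cell sets relabeled: all fold changes zero, nothing significant
  dup <- scpbench:::subset_cm(p$nm, j = rep(seq_len(50), 2))
  dup$cell_meta$barcode <- paste0(dup$cell_meta$barcode, seq_len(100))
  colnames(dup$counts) <- dup$cell_meta$barcode
  de0 <- differential_expression(dup, protocol_labels = rep(c("A", "B"), each = 50))
  expect_equal(max(abs(de0$log2fc)), 0)
  expect_equal(sum(de0$significant), 0)

  # presence rule: a gene under 10% in both groups is not tested
  nm <- p$nm
  rare <- which(pmax(Matrix::rowSums(nm$counts[, nm$cell_meta$protocol == "A"] > 0) / sum(nm$cell_meta$protocol == "A"),
                     Matrix::rowSums(nm$counts[, nm$cell_meta$protocol == "B"] > 0) / sum(nm$cell_meta$protocol == "B")) < 0.10)
  de <- differential_expression(nm)
  if (length(rare)) {
    expect_false(any(de$tested[rare]))
    expect_true(all(is.na(de$p_value[rare])))
  }
  expect_error(differential_expression(nm, protocol_labels = c(rep("A", 2), rep("B", ncol(nm$counts) - 2))),
               ">= 3 cells")
})

test_that("label swap negates fold changes and preserves p-values", {
  p <- norm_pair(seed = 6, stress_fold = 2)
  labs <- p$nm$cell_meta$protocol
  de_ab <- differential_expression(p$nm, protocol_labels = labs)
  swapped <- factor(ifelse(labs == "A", "B", "A"), levels = c("A", "B"))
  de_ba <- differential_expression(p$nm, protocol_labels = as.character(swapped))
  expect_equal(de_ba$log2fc, -de_ab$log2fc)
  expect_equal(de_ba$p_value, de_ab$p_value)
  expect_equal(de_ba$significant, de_ab$significant)
})

test_that("planted fold-change genes are recovered with error control", {
  spec <- synthetic_spec(stress_fold = 4, seed = 51)   # 300 cells/arm, 2000 genes
  nm <- normalize_log(filter_genes(simulate_count_pair(spec), 1))
  de <- differential_expression(nm)
  planted <- de$gene_id %in% spec$stress_gene_ids
  expect_gte(mean(de$significant[planted]), 0.9)
  expect_lte(sum(de$significant[!planted]), 2)
  # direction: planted genes are up in the stressed arm (A)
  expect_true(all(de$log2fc[planted & de$significant] > 0))
})

test_that("gene category breakdown partitions genes with unit fractions", {
  bt <- c(g1 = "protein_coding", g2 = "lncRNA", g3 = "protein_coding",
          g4 = "pseudogene", g5 = "protein_coding")
  res <- gene_category_breakdown(c("g1", "g2", "g3", "g6"), c("g2", "g3", "g4"), bt)
  expect_equal(unname(res$counts), c(2L, 2L, 1L))
  expect_equal(res$fractions$shared[["lncRNA"]], 0.5)
  expect_equal(res$fractions$unique_a[["unannotated"]], 0.5)  # g6 unmapped
  expect_equal(sum(res$fractions$unique_b), 1)

  same <- gene_category_breakdown(c("g1", "g2"), c("g1", "g2"), bt)
  expect_equal(unname(same$counts[c("unique_a", "unique_b")]), c(0L, 0L))
})
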