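# Independent oracle: exhaustive enumeration of all C(R, n) read subsets,
# returning each molecule's survival probability (>= 1 read kept).
enumerate_survival <- function(read_counts, n) {
  mol_of_read <- rep(seq_along(read_counts), read_counts)
  subsets <- utils::combn(length(mol_of_read), n)
  survived <- matrix(FALSE, length(read_counts), ncol(subsets))
  for (j in seq_len(ncol(subsets)))
    survived[unique(mol_of_read[subsets[, j]]), j] <- TRUE
  rowMeans(survived)
}

test_that("downsampler matches the exhaustive hypergeometric oracle", {
  # (3,2,1) reads, draw 3 of 6: the 1-read molecule survives in half of the
  # C(6,3) = 20 subsets
  oracle <- enumerate_survival(c(3, 2, 1), 3)
  expect_equal(oracle[3], 1 / 2)

  tab <- tiny_table()
  draws <- vapply(seq_len(4000), function(s) {
    sub <- downsample_reads(tab, 3, seed = s)
    c("u3" %in% sub$umi, "u1" %in% sub$umi, "u2" %in% sub$umi)
  }, logical(3))
  emp <- rowMeans(draws)
  se <- sqrt(oracle * (1 - oracle) / 4000)
  expect_true(all(abs(emp - oracle[c(3, 1, 2)]) < 3 * se[c(3, 1, 2)]))

  # a second instance with uneven pools, all survival probabilities at once
  rc <- c(4, 1, 1, 2)
  oracle2 <- enumerate_survival(rc, 4)
  tab2 <- molecule_table(rep("b", 4), paste0("u", 1:4), paste0("g", 1:4), rc)
  emp2 <- rowMeans(vapply(seq_len(4000), function(s) {
    sub <- downsample_reads(tab2, 4, seed = s)
    paste0("u", 1:4) %in% sub$umi
  }, logical(4)))
  expect_true(all(abs(emp2 - oracle2) < 3 * sqrt(oracle2 * (1 - oracle2) / 4000) + 1e-12))
})

test_that("downsampling keeps exact totals and honours the boundary depths", {
  pair <- small_molecule_pair(seed = 2)
  tab <- pair$sim$table_a
  R <- total_reads(tab)
  expect_identical(downsample_reads(tab, R, seed = 1), tab)  # full depth
  empty <- downsample_reads(tab, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  for (d in c(1, 57, round(R / 3))) {
    sub <- downsample_reads(tab, d, seed = d)
    expect_equal(total_reads(sub), d)
    expect_true(all(sub$read_count >= 1))
    # surviving molecules are a subset with non-increased read counts
    key <- function(t) paste(t$cell_barcode, t$umi, t$gene_id)
    idx <- match(key(sub), key(tab))
    expect_false(anyNA(idx))
    expect_true(all(sub$read_count <= tab$read_count[idx]))
  }
  expect_error(downsample_reads(tab, R + 1), "exceeds total reads")
})

test_that("saturation curve ends at library totals and recounts agree", {
  pair <- small_molecule_pair(seed = 8)
  tab <- pair$sim$table_a
  cur <- saturation_curve(tab, n_steps = 6, seed = 3)
  expect_equal(cur$depth[nrow(cur)], total_reads(tab))
  expect_equal(cur$genes_detected[nrow(cur)], length(unique(tab$gene_id)))
  expect_equal(cur$umis_detected[nrow(cur)], nrow(tab))

  # single-point grid at full depth
  one <- saturation_curve(tab, depth_grid = total_reads(tab))
  expect_equal(nrow(one), 1L)
  expect_equal(one$umis_detected, nrow(tab))

  # independent recount oracle: collapse the downsampled table and re-count
  d <- round(total_reads(tab) / 2)
  sub <- downsample_reads(tab, d, seed = 103)  # same child seed path not needed
  cm <- collapse_to_matrix(sub)
  expect_equal(length(unique(sub$gene_id)), nrow(cm$counts))
  expect_equal(nrow(sub), sum(cm$counts))

  expect_error(saturation_curve(molecule_table(character(), character(),
                                               character(), integer())),
               "empty")
})

test_that("nested downsampling is monotone in depth", {
  pair <- small_molecule_pair(seed = 12)
  tab <- pair$sim$table_a
  depths <- round(seq(0.1, 1, by = 0.15) * total_reads(tab))
  subs <- scpbench:::downsample_reads_nested(tab, depths, seed = 5)
  genes <- vapply(subs, function(t) length(unique(t$gene_id)), integer(1))
  umis <- vapply(subs, nrow, integer(1))
  expect_true(all(diff(genes) >= 0))
  expect_true(all(diff(umis) >= 0))
})

test_that("depth model reproduces hand-computed OLS and its 95% CI", {
  # exact line: zero-width CI around the true slope
  cur <- structure(data.frame(depth = c(1, 2, 3), genes_detected = c(3, 5, 7),
                              umis_detected = c(3, 5, 7)),
                   class = c("saturation_curve", "data.frame"))
  fit <- fit_depth_model(cur, "genes")
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(fit$slope_ci_high - fit$slope_ci_low, 1e-8)

  # textbook OLS on (1,1),(2,2),(3,2): slope 1/2, intercept 2/3,
  # SE = sqrt(s^2/Sxx) with s^2 = (1/6)/(3-2) = 1/6, Sxx = 2
  cur2 <- structure(data.frame(depth = c(1, 2, 3), genes_detected = c(1, 2, 2),
                               umis_detected = c(1, 2, 2)),
                    class = c("saturation_curve", "data.frame"))
  fit2 <- fit_depth_model(cur2, "genes")
  half_width <- qt(0.975, df = 1) * sqrt((1 / 6) / 2)
  expect_equal(fit2$slope, 0.5)
  expect_equal(fit2$intercept, 2 / 3)
  expect_equal(fit2$slope_ci_low, 0.5 - half_width, tolerance = 1e-8)
  expect_equal(fit2$slope_ci_high, 0.5 + half_width, tolerance = 1e-8)

  # point order is irrelevant
  cur3 <- cur2[c(3, 1, 2), ]
  expect_equal(fit_depth_model(cur3, "genes")$slope, fit2$slope)

  expect_error(fit_depth_model(cur2[1:2, ], "genes"), ">= 3 points")
})

test_that("CI-overlap verdicts follow closed-interval arithmetic", {
  mk <- function(lo, hi) scpbench:::linear_fit_ci((lo + hi) / 2, 0, lo, hi, 1, 5)
  expect_false(ci_overlap_test(mk(1, 2), mk(1, 2))$significant)  # identical
  expect_true(ci_overlap_test(mk(1, 2), mk(3, 4))$significant)   # disjoint
  expect_false(ci_overlap_test(mk(1, 3), mk(2, 4))$significant)  # overlap
  expect_false(ci_overlap_test(mk(1, 2), mk(2, 3))$significant)  # touching
  # symmetry
  expect_equal(ci_overlap_test(mk(1, 2), mk(3, 4))$significant,
               ci_overlap_test(mk(3, 4), mk(1, 2))$significant)
})

test_that("per-cell complexity tabulates and fits per-barcode points", {
  # collinear 4-cell fixture: genes = reads/10 exactly
  rc <- c(10, 20, 30, 40)
  rows <- unlist(lapply(seq_along(rc), function(i)
    rep(sprintf("b%d", i), rc[i] / 10)))
  tab <- molecule_table(rows, paste0("u", seq_along(rows)),
                        paste0("g", unlist(lapply(rc / 10, seq_len))),
                        rep(10L, length(rows)))
  pcc <- per_cell_complexity(tab)
  expect_equal(pcc$per_cell$reads, rc)
  expect_equal(pcc$per_cell$genes, rc / 10)
  expect_equal(pcc$fit_genes$slope, 1 / 10)
  expect_lt(pcc$fit_genes$slope_ci_high - pcc$fit_genes$slope_ci_low, 1e-8)

  # per-cell umis equal collapsed row sums
  pair <- small_molecule_pair(seed = 3)
  pcc2 <- per_cell_complexity(pair$sim$table_a)
  cm <- collapse_to_matrix(pair$sim$table_a)
  expect_equal(pcc2$per_cell$umis,
               as.integer(Matrix::colSums(cm$counts)[pcc2$per_cell$barcode]))

  # identical cells: zero-variance predictor is flagged, not fitted
  tab3 <- molecule_table(rep(c("b1", "b2", "b3"), each = 2),
                         rep(c("u1", "u2"), 3),
                         rep(c("g1", "g2"), 3), rep(1L, 6))
  pcc3 <- per_cell_complexity(tab3)
  expect_true(pcc3$fit_genes$degenerate)
  expect_true(is.na(pcc3$fit_genes$slope))
})

test_that("gene accumulation matches exhaustive pair enumeration on the toy", {
  # cells with gene sets {A,B}, {B,C}, {C}: mean over all pairs = 8/3
  cm <- matrix_from_gene_sets(list(c("A", "B"), c("B", "C"), "C"))
  pairs <- utils::combn(3, 2)
  sets <- list(c("A", "B"), c("B", "C"), "C")
  exact <- mean(apply(pairs, 2, function(p) length(union(sets[[p[1]]], sets[[p[2]]]))))
  expect_equal(exact, 8 / 3)

  acc <- cumulative_gene_curve(cm, n_grid = c(1, 2, 3), reps = 100, seed = 42)
  sd_pair <- sd(apply(pairs, 2, function(p) length(union(sets[[p[1]]], sets[[p[2]]]))))
  expect_lt(abs(acc$mean_genes[2] - exact), 3 * sd_pair / sqrt(100) + 1e-12)

  # at n = all cells the union is deterministic and complete
  expect_equal(acc$mean_genes[3], 3)
  expect_equal(acc$sd_genes[3], 0)

  # single shared gene: curve constant at 1
  cm1 <- matrix_from_gene_sets(list("A", "A", "A"))
  acc1 <- cumulative_gene_curve(cm1, n_grid = c(1, 2, 3), reps = 10, seed = 1)
  expect_equal(acc1$mean_genes, c(1, 1, 1))

  # monotone in n, errors beyond the cell count
  pair <- small_count_pair(seed = 5)
  accs <- cumulative_gene_curve(pair$cm, n_grid = seq(1, 41, 4), reps = 20, seed = 2)
  expect_true(all(diff(accs$mean_genes) >= 0))
  expect_error(cumulative_gene_curve(cm, n_grid = c(2, 10), reps = 5, seed = 1),
               "only 3")
})
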