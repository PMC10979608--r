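test_that("simulation is deterministic and conserves molecules", {
  spec <- synthetic_spec(n_cell_types = 2, cells_per_type_per_protocol = 10,
                         n_genes = 100, library_size_log_mean = log(200),
                         seed = 3)
  s1 <- simulate_protocol_pair(spec)
  s2 <- simulate_protocol_pair(spec)
  expect_identical(s1, s2)

  # collapsing preserves molecule counts; reads >= molecules
  cmA <- collapse_to_matrix(s1$table_a)
  expect_equal(sum(cmA$counts), nrow(s1$table_a))
  expect_true(all(s1$table_a$read_count >= 1))
  expect_equal(total_reads(s1$table_a), sum(s1$table_a$read_count))

  # truth labels cover every barcode exactly once
  bcs <- c(unique(s1$table_a$cell_barcode), unique(s1$table_b$cell_barcode))
  expect_setequal(s1$truth$barcode, bcs)
  expect_false(any(duplicated(s1$truth$barcode)))

  # count-level generator agrees with the collapsed molecule-level one
  cm <- simulate_count_pair(spec)
  a_cells <- cm$cell_meta$protocol == "A"
  expect_equal(sum(cm$counts[, a_cells]), nrow(s1$table_a))
})

test_that("amplification floor of one read holds and mean is honoured", {
  spec <- synthetic_spec(n_cell_types = 1, cells_per_type_per_protocol = 30,
                         n_genes = 100, library_size_log_mean = log(300),
                         amplification_mean = 1, seed = 5)
  sim <- simulate_protocol_pair(spec)
  expect_true(all(sim$table_a$read_count == 1L))  # mean 1 => no amplification

  spec4 <- synthetic_spec(n_cell_types = 1, cells_per_type_per_protocol = 30,
                          n_genes = 100, library_size_log_mean = log(300),
                          amplification_mean = 4, seed = 5)
  sim4 <- simulate_protocol_pair(spec4)
  expect_gt(mean(sim4$table_a$read_count), 3.5)
  expect_lt(mean(sim4$table_a$read_count), 4.5)
})

test_that("planted stress fold matches the analytic multinomial expectation", {
  # one cell type so every stress gene has the same closed-form log2 fold:
  # A's proportions are 4r/(T + 3S), B's r/T  =>  log2FC = 2 - log2(1 + 3S/T)
  spec <- synthetic_spec(n_cell_types = 1, cells_per_type_per_protocol = 300,
                         n_genes = 2000, stress_fold = 4, seed = 11)
  rates <- scpbench:::sim_rates(spec)[, 1]
  S <- sum(rates[spec$stress_gene_ids])
  T_tot <- sum(rates)
  analytic <- 2 - log2(1 + 3 * S / T_tot)
  expect_lt(abs(analytic - 2), 0.2)  # small stress mass => near the nominal fold

  cm <- simulate_count_pair(spec)
  a <- cm$cell_meta$protocol == "A"
  prop_a <- Matrix::rowSums(cm$counts[, a]) / sum(cm$counts[, a])
  prop_b <- Matrix::rowSums(cm$counts[, !a]) / sum(cm$counts[, !a])
  emp <- log2(prop_a[spec$stress_gene_ids] / prop_b[spec$stress_gene_ids])
  expect_lt(abs(mean(emp) - analytic), 0.1)  # Monte-Carlo error at this depth
})

test_that("null configuration gives exchangeable protocols", {
  spec <- synthetic_spec(n_cell_types = 2, cells_per_type_per_protocol = 100,
                         n_genes = 500, stress_fold = 1, seed = 21)
  cm <- simulate_count_pair(spec)
  a <- cm$cell_meta$protocol == "A"
  prop_a <- Matrix::rowSums(cm$counts[, a]) / sum(cm$counts[, a])
  prop_b <- Matrix::rowSums(cm$counts[, !a]) / sum(cm$counts[, !a])
  both <- prop_a > 0 & prop_b > 0
  lfc <- log2(prop_a[both] / prop_b[both])
  expect_lt(abs(mean(lfc)), 0.05)
  stress <- names(prop_a) %in% spec$stress_gene_ids & both
  expect_lt(abs(mean(lfc[stress[both]])), 0.3)
})

test_that("spec validation catches inconsistent parameterizations", {
  expect_error(synthetic_spec(n_cell_types = 2,
                              cells_per_type_per_protocol = matrix(0, 2, 2)),
               "no cells for protocol")
  expect_error(synthetic_spec(stress_gene_ids = "NOT_A_GENE"),
               "stress gene not in gene universe")
  expect_error(synthetic_spec(stress_fold = 0), "stress_fold")
  expect_error(synthetic_spec(lowq_fraction = 1.5), "lowq_fraction")
  expect_error(synthetic_spec(lowq_fraction = 0.1, n_mt_genes = 0),
               "mt_gene_ids empty")
})

test_that("low-quality planting flags the exact count and boosts MT content", {
  spec <- synthetic_spec(n_cell_types = 1, cells_per_type_per_protocol = 50,
                         n_genes = 150, library_size_log_mean = log(300),
                         lowq_fraction = 0.1, seed = 2)
  sim <- simulate_protocol_pair(spec)
  expect_equal(sum(sim$truth$low_quality[sim$truth$protocol == "A"]), 5)

  # zero fraction leaves the table untouched
  spec0 <- synthetic_spec(n_cell_types = 1, cells_per_type_per_protocol = 20,
                          n_genes = 100, seed = 2, lowq_fraction = 0)
  tab <- simulate_protocol_pair(spec0)$table_a
  out <- plant_low_quality_cells(tab, spec0)
  expect_identical(out$table, tab)
  expect_length(out$flagged, 0)

  # boost mechanics: flagged cells exceed the unflagged median MT% and sit
  # below the 5th percentile of unflagged totals, across seeds
  hits_mt <- hits_umi <- logical(50)
  for (s in seq_len(50)) {
    sp <- synthetic_spec(n_cell_types = 1, cells_per_type_per_protocol = 40,
                         n_genes = 150, library_size_log_mean = log(300),
                         lowq_fraction = 0.1, seed = 100 + s)
    si <- simulate_protocol_pair(sp)
    cm <- collapse_to_matrix(si$table_a, gene_meta = scpbench:::sim_gene_meta(sp))
    qc <- compute_qc(cm)
    lq <- si$truth$low_quality[match(qc$barcode, si$truth$barcode)]
    hits_mt[s] <- min(qc$pct_mt[lq]) > median(qc$pct_mt[!lq])
    hits_umi[s] <- max(qc$n_umi[lq]) < quantile(qc$n_umi[!lq], 0.05)
  }
  expect_gte(mean(hits_mt), 0.95)
  expect_gte(mean(hits_umi), 0.9)
})

test_that("written simulations round-trip through the on-disk formats", {
  pair <- small_molecule_pair(seed = 9)
  dir <- withr::local_tempdir()
  write_simulation(pair$sim, pair$spec, dir)
  back <- read_molecule_table(file.path(dir, "molecules_A.tsv"))
  expect_equal(as.data.frame(back)[order(back$cell_barcode, back$gene_id, back$umi), ],
               as.data.frame(pair$sim$table_a)[order(pair$sim$table_a$cell_barcode,
                                                     pair$sim$table_a$gene_id,
                                                     pair$sim$table_a$umi), ],
               ignore_attr = TRUE)
  cm <- read_mtx(file.path(dir, "counts_A"))
  expect_equal(sum(cm$counts), nrow(pair$sim$table_a))
})
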