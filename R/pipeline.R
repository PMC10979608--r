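#' Benchmark configuration
#'
#' Declarative description of a full protocol-comparison run: the synthetic
#' generative spec (or paths to on-disk inputs), which stages to execute, and
#' every stage parameter. All defaults are echoed into the report for
#' provenance.
#'
#' @param simulation list of [synthetic_spec()] arguments, or an already
#'   constructed spec.
#' @param stages character subset of
#'   `c("equalize", "saturation", "qc", "compare", "signatures", "gsea")`.
#' @param seed master seed for the whole run (overrides the spec seed).
#' @param out_dir output directory for stage files and the report.
#' @param saturation,qc,hvg,correlation,de,signatures,gsea named lists of
#'   stage parameters; unset entries take the documented defaults.
#' @param gene_sets optional named list of gene sets for the enrichment
#'   stage; by default the spec's stress set plus seeded random sets.
#' @return A `bench_config` list.
#' @export
bench_config <- function(simulation = list(),
                         stages = c("equalize", "saturation", "qc", "compare",
                                    "signatures", "gsea"),
                         seed = 1L, out_dir = tempfile("benchrun"),
                         saturation = list(), qc = list(), hvg = list(),
                         correlation = list(), de = list(),
                         signatures = list(), gsea = list(),
                         gene_sets = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  spec <- if (inherits(simulation, "synthetic_spec")) simulation
          else do.call(synthetic_spec, simulation)
  spec$seed <- as.integer(seed)
  defaults <- list(
    saturation = list(n_steps = 8, accumulation_reps = 50, accumulation_max = 60),
    qc = list(min_gene = 100, min_umi = 200, max_pct_mt = 25,
              preset = NULL, min_cells = 3, norm_scale = 1e4),
    hvg = list(n_top = 500),
    correlation = list(min_total = 100, min_per_cond = 20, downsample = TRUE),
    de = list(min_pct = 0.10, logfc_min = 1, alpha = 0.05),
    signatures = list(r_max = 1500, max_cells_per_type = 250),
    gsea = list(min_size = 10, max_size = 300, n_perm = 500, p_weight = 1,
                n_random_sets = 10))
  merge_params <- function(user, def) utils::modifyList(def, user)
  structure(list(spec = spec, stages = stages, seed = as.integer(seed),
                 out_dir = out_dir,
                 saturation = merge_params(saturation, defaults$saturation),
                 qc = merge_params(qc, defaults$qc),
                 hvg = merge_params(hvg, defaults$hvg),
                 correlation = merge_params(correlation, defaults$correlation),
                 de = merge_params(de, defaults$de),
                 signatures = merge_params(signatures, defaults$signatures),
                 gsea = merge_params(gsea, defaults$gsea),
                 gene_sets = gene_sets),
            class = "bench_config")
}

#' Run the full protocol-comparison benchmark
#'
#' Executes the configured stages in dependency order — simulate, equalize
#' depth, saturation analysis, QC + normalization + HVG overlap, comparison
#' statistics (pseudo-bulk correlation, composition, differential
#' expression), signature scoring and pre-ranked enrichment — writing stage
#' outputs under `config$out_dir` and returning (and writing) a
#' machine-readable report. The report contains no timestamps, so identical
#' config + seed reproduce it byte-identically.
#'
#' @param config a [bench_config()].
#' @return A `bench_report` list (also written as `report.json`).
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "bench_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec
  stages <- config$stages
  report <- list(
    package_version = as.character(utils::packageVersion("scpbench")),
    seed = config$seed,
    stages_run = stages,
    substitutions = c(
      "differential expression: Wilcoxon rank-sum in place of a hurdle model",
      "composition: descriptive proportions + bootstrap CI in place of a Bayesian compositional model"),
    files = list(), verdicts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- stage("simulate", simulate_protocol_pair(spec))
  tables <- list(A = sim$table_a, B = sim$table_b)
  write_simulation(sim, spec, file.path(config$out_dir, "sim"))
  report$files$simulation <- "sim"

  if ("equalize" %in% stages) {
    tables <- stage("equalize",
                    setNames(equalize_depth(tables, seed = child_seed(config$seed, 2L)),
                             names(tables)))
    report$verdicts$mean_reads_per_barcode <- lapply(tables, function(t)
      total_reads(t) / length(unique(t$cell_barcode)))
  }

  if ("saturation" %in% stages) {
    sp <- config$saturation
    res <- stage("saturation", {
      fits <- lapply(names(tables), function(p) {
        cur <- saturation_curve(tables[[p]], n_steps = sp$n_steps,
                                seed = child_seed(config$seed, 3L + match(p, names(tables))))
        data.table::fwrite(as.data.frame(cur),
                           file.path(config$out_dir, sprintf("saturation_%s.tsv", p)),
                           sep = "\t")
        list(genes = fit_depth_model(cur, "genes"),
             umis = fit_depth_model(cur, "umis"))
      })
      names(fits) <- names(tables)
      list(fits = fits,
           genes_verdict = ci_overlap_test(fits$A$genes, fits$B$genes),
           umis_verdict = ci_overlap_test(fits$A$umis, fits$B$umis))
    })
    report$files$saturation <- sprintf("saturation_%s.tsv", names(tables))
    report$verdicts$saturation <- list(
      slope_genes = lapply(res$fits, function(f) unclass(f$genes)),
      slope_umis = lapply(res$fits, function(f) unclass(f$umis)),
      genes_ci_disjoint = res$genes_verdict$significant,
      umis_ci_disjoint = res$umis_verdict$significant)
  }

  gm <- sim_gene_meta(spec)
  cm <- stage("collapse", {
    mats <- lapply(tables, collapse_to_matrix, gene_meta = gm)
    combine_pair(mats$A, mats$B, sim$truth, gm)
  })

  norm <- NULL
  if ("qc" %in% stages) {
    qp <- config$qc
    res <- stage("qc", {
      metrics <- compute_qc(cm)
      th <- qc_thresholds(min_umi = qp$min_umi, min_gene = qp$min_gene,
                          max_pct_mt = if (is.null(qp$preset)) qp$max_pct_mt else NULL,
                          preset = qp$preset)
      kept <- filter_cells(cm, metrics, th)
      cm2 <- subset_cm(cm, j = match(kept$kept, cm$cell_meta$barcode))
      cm2 <- filter_genes(cm2, min_cells = qp$min_cells)
      norm <- normalize_log(cm2, scale = qp$norm_scale)
      hv <- lapply(c("A", "B"), function(p)
        select_hvgs(subset_cm(cm2, j = which(cm2$cell_meta$protocol == p)),
                    n_top = config$hvg$n_top))
      list(metrics = metrics, tally = kept$tally, n_kept = length(kept$kept),
           hvg_overlap = hvg_overlap(hv[[1]], hv[[2]], n = config$hvg$n_top))
    })
    data.table::fwrite(res$metrics, file.path(config$out_dir, "qc_metrics.tsv"), sep = "\t")
    report$files$qc <- "qc_metrics.tsv"
    report$verdicts$qc <- list(cells_kept = res$n_kept,
                               removal_tally = as.list(res$tally),
                               hvg_overlap = res$hvg_overlap)
  }

  needs_norm <- any(c("compare", "signatures", "gsea") %in% stages)
  if (needs_norm && is.null(norm))
    norm <- stage("normalize", normalize_log(filter_genes(cm, 1),
                                             scale = config$qc$norm_scale))
  de <- NULL
  if ("compare" %in% stages) {
    cp <- config$correlation
    res <- stage("compare", {
      corr <- pseudobulk_correlation(norm,
                                     cell_type_labels = norm$cell_meta$cell_type,
                                     min_total = cp$min_total,
                                     min_per_cond = cp$min_per_cond,
                                     downsample = cp$downsample,
                                     seed = child_seed(config$seed, 7L))
      comp <- composition_compare(norm$cell_meta$cell_type,
                                  norm$cell_meta$protocol,
                                  seed = child_seed(config$seed, 8L))
      de <- differential_expression(norm, min_pct = config$de$min_pct,
                                     logfc_min = config$de$logfc_min,
                                     alpha = config$de$alpha)
      list(corr = corr, comp = comp)
    })
    data.table::fwrite(res$corr, file.path(config$out_dir, "correlation.tsv"), sep = "\t")
    data.table::fwrite(res$comp, file.path(config$out_dir, "composition.tsv"), sep = "\t")
    data.table::fwrite(de, file.path(config$out_dir, "de.tsv"), sep = "\t")
    report$files$compare <- c("correlation.tsv", "composition.tsv", "de.tsv")
    g <- res$corr[res$corr$scope == "global", ]
    report$verdicts$compare <- list(
      global_r_squared = g$r_squared, global_passed_strong = g$passed_strong,
      n_strong_scopes = sum(res$corr$passed_strong, na.rm = TRUE),
      n_de_significant = sum(de$significant, na.rm = TRUE),
      composition = res$comp[, c("cell_type", "prop_a", "prop_b", "log2_ratio",
                                 "ci_low", "ci_high")])
  }

  if ("signatures" %in% stages) {
    sg <- config$signatures
    res <- stage("signatures", {
      sc <- score_signature(norm, intersect(spec$stress_gene_ids, rownames(norm$counts)),
                            r_max = min(sg$r_max, nrow(norm$counts) - 1),
                            signature_name = "stress")
      compare_scores(sc, norm$cell_meta$protocol, norm$cell_meta$cell_type,
                     max_cells_per_type = sg$max_cells_per_type,
                     seed = child_seed(config$seed, 9L))
    })
    data.table::fwrite(res, file.path(config$out_dir, "signature_comparison.tsv"), sep = "\t")
    report$files$signatures <- "signature_comparison.tsv"
    g <- res[res$scope == "global", ]
    report$verdicts$signatures <- list(global_p = g$p_value,
                                       global_median_diff = g$median_diff)
  }

  if ("gsea" %in% stages) {
    gp <- config$gsea
    res <- stage("gsea", {
      if (is.null(de))
        de <- differential_expression(norm, min_pct = config$de$min_pct)
      stats <- de_rank_statistic(de)
      sets <- config$gene_sets %||% c(
        list(stress = spec$stress_gene_ids),
        with_seed_(child_seed(config$seed, 10L),
          setNames(lapply(seq_len(gp$n_random_sets), function(i)
            sample(names(stats), 30)),
            sprintf("random%02d", seq_len(gp$n_random_sets)))))
      preranked_gsea(stats, sets, min_size = gp$min_size,
                     max_size = min(gp$max_size, length(stats)),
                     n_perm = gp$n_perm,
                     p_weight = gp$p_weight,
                     seed = child_seed(config$seed, 11L))
    })
    data.table::fwrite(res, file.path(config$out_dir, "gsea.tsv"), sep = "\t")
    report$files$gsea <- "gsea.tsv"
    report$verdicts$gsea <- list(
      n_tested = sum(!res$excluded),
      n_significant = sum(res$significant, na.rm = TRUE),
      stress_p = if ("stress" %in% res$set) res$p_value[res$set == "stress"] else NULL)
  }

  report$config <- config_provenance(config)
  class(report) <- "bench_report"
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  report
}

# Serializable echo of every configuration value, for provenance.
config_provenance <- function(config) {
  spec <- config$spec
  spec$cells_per_type_per_protocol <-
    as.data.frame(spec$cells_per_type_per_protocol)
  c(list(spec = unclass(spec)[setdiff(names(spec), "gene_ids")],
         stages = config$stages, seed = config$seed),
    config[c("saturation", "qc", "hvg", "correlation", "de",
             "signatures", "gsea")])
}

# Combine the two protocol matrices over the shared gene universe and attach
# truth labels.
combine_pair <- function(ma, mb, truth, gene_meta) {
  genes <- gene_meta$gene_id
  expand <- function(x) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(genes), ncol(x$counts)),
                              dimnames = list(genes, colnames(x$counts)))
    m[rownames(x$counts), ] <- x$counts
    m
  }
  m <- cbind(expand(ma), expand(mb))
  meta <- truth[match(colnames(m), truth$barcode), , drop = FALSE]
  count_matrix(m, cell_meta = meta, gene_meta = gene_meta)
}

#' @export
print.bench_report <- function(x, ...) {
  cat("bench_report (stages:", paste(x$stages_run, collapse = ", "), ")\n")
  v <- x$verdicts
  if (!is.null(v$saturation))
    cat(sprintf("  saturation: genes CI disjoint = %s, umis CI disjoint = %s\n",
                v$saturation$genes_ci_disjoint, v$saturation$umis_ci_disjoint))
  if (!is.null(v$qc))
    cat(sprintf("  qc: %d cells kept, HVG overlap = %.3f\n",
                v$qc$cells_kept, v$qc$hvg_overlap))
  if (!is.null(v$compare))
    cat(sprintf("  compare: global r^2 = %.4f (strong: %s), %d sDE genes\n",
                v$compare$global_r_squared, v$compare$global_passed_strong,
                v$compare$n_de_significant))
  if (!is.null(v$signatures))
    cat(sprintf("  signatures: global p = %.3g\n", v$signatures$global_p))
  if (!is.null(v$gsea))
    cat(sprintf("  gsea: %d/%d sets significant\n",
                v$gsea$n_significant, v$gsea$n_tested))
  invisible(x)
}
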