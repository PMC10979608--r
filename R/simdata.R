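#' Generative specification for paired-protocol synthetic libraries
#'
#' Describes a two-protocol single-cell experiment with known ground truth:
#' protocol "A" is the stressed (fresh-analogue) arm, protocol "B" the
#' protected (fixed-analogue) arm. Gene abundance is log-normal with
#' independent per-cell-type multiplicative perturbations; per-cell totals are
#' log-normal; molecules are amplified into reads by a shifted negative
#' binomial (every molecule keeps >= 1 read). Stress genes have their rates
#' multiplied by `stress_fold` in protocol A only, and an optional fraction of
#' cells is degraded into high-mitochondrial, low-UMI barcodes for QC testing.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type_per_protocol integer matrix (type x protocol, columns
#'   "A","B") of cell numbers; a scalar is recycled.
#' @param n_genes size of the gene universe (includes mitochondrial genes).
#' @param base_rate_log_mean,base_rate_log_sd log-normal parameters of the
#'   per-gene base abundance rates (arbitrary rate units).
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   per-cell total UMI counts.
#' @param type_effect_sd sd of the per-type log-normal rate multipliers.
#' @param n_stress_genes,stress_gene_ids stress gene set: either a count
#'   (genes picked deterministically from the universe) or explicit ids.
#' @param stress_fold multiplier (> 0) applied to stress-gene rates in
#'   protocol A.
#' @param n_mt_genes,mt_gene_ids mitochondrial gene set, as above; mt gene ids
#'   carry an `MT-` prefix so downstream QC recognises them.
#' @param lowq_fraction fraction of barcodes per protocol degraded to
#'   low-quality (high MT, low UMI).
#' @param lowq_mt_boost multiplier (> 1) on the expected mitochondrial
#'   fraction of degraded cells.
#' @param amplification_mean mean sequenced reads per molecule (>= 1).
#' @param amplification_dispersion negative-binomial size parameter of the
#'   read-amplification distribution (> 0; smaller = more dispersed).
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cell_types = 4,
                           cells_per_type_per_protocol = 75,
                           n_genes = 2000,
                           base_rate_log_mean = 0,
                           base_rate_log_sd = 1,
                           library_size_log_mean = log(2500),
                           library_size_log_sd = 0.35,
                           type_effect_sd = 0.4,
                           n_stress_genes = 20,
                           stress_gene_ids = NULL,
                           stress_fold = 1,
                           n_mt_genes = 13,
                           mt_gene_ids = NULL,
                           lowq_fraction = 0,
                           lowq_mt_boost = 3,
                           amplification_mean = 4,
                           amplification_dispersion = 1,
                           seed = 1L) {
  if (length(cells_per_type_per_protocol) == 1L)
    cells_per_type_per_protocol <- matrix(cells_per_type_per_protocol,
                                          n_cell_types, 2)
  cells <- as.matrix(cells_per_type_per_protocol)
  if (is.null(colnames(cells))) colnames(cells) <- c("A", "B")
  if (nrow(cells) != n_cell_types)
    stopf("cells_per_type_per_protocol has %d rows for %d cell types",
          nrow(cells), n_cell_types)

  n_mt <- if (is.null(mt_gene_ids)) n_mt_genes else length(mt_gene_ids)
  genes <- c(sprintf("GENE%05d", seq_len(n_genes - n_mt)),
             sprintf("MT-%02d", seq_len(n_mt)))
  if (is.null(mt_gene_ids)) mt_gene_ids <- genes[grepl("^MT-", genes)]
  if (is.null(stress_gene_ids)) {
    pool <- setdiff(genes, mt_gene_ids)
    stress_gene_ids <- pool[round(seq(1, length(pool), length.out = n_stress_genes))]
  }

  spec <- structure(list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type_per_protocol = cells,
    n_genes = as.integer(n_genes),
    gene_ids = genes,
    base_rate_log_mean = base_rate_log_mean,
    base_rate_log_sd = base_rate_log_sd,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    type_effect_sd = type_effect_sd,
    stress_gene_ids = stress_gene_ids,
    stress_fold = stress_fold,
    mt_gene_ids = mt_gene_ids,
    lowq_fraction = lowq_fraction,
    lowq_mt_boost = lowq_mt_boost,
    amplification_mean = amplification_mean,
    amplification_dispersion = amplification_dispersion,
    seed = as.integer(seed)), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  cells <- spec$cells_per_type_per_protocol
  if (any(cells < 0)) stopf("negative cell counts in composition table")
  if (any(colSums(cells) == 0)) stopf("no cells for protocol")
  if (!all(spec$stress_gene_ids %in% spec$gene_ids))
    stopf("stress gene not in gene universe: %s",
          setdiff(spec$stress_gene_ids, spec$gene_ids)[1])
  if (!all(spec$mt_gene_ids %in% spec$gene_ids))
    stopf("mt gene not in gene universe: %s",
          setdiff(spec$mt_gene_ids, spec$gene_ids)[1])
  if (spec$stress_fold <= 0) stopf("stress_fold must be > 0")
  if (spec$lowq_fraction < 0 || spec$lowq_fraction > 1)
    stopf("lowq_fraction must be in [0, 1]")
  if (spec$lowq_fraction > 0 && length(spec$mt_gene_ids) == 0)
    stopf("mt_gene_ids empty while lowq_fraction > 0")
  if (spec$amplification_mean < 1) stopf("amplification_mean must be >= 1")
  if (spec$amplification_dispersion <= 0)
    stopf("amplification_dispersion must be > 0")
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_spec: %d cell types, %d genes ",
                     "(%d stress, %d mito), cells/protocol A=%d B=%d,\n",
                     "  stress_fold=%g, lowq_fraction=%g, ",
                     "amplification mean=%g reads/molecule, seed=%d\n"),
              x$n_cell_types, x$n_genes, length(x$stress_gene_ids),
              length(x$mt_gene_ids),
              sum(x$cells_per_type_per_protocol[, "A"]),
              sum(x$cells_per_type_per_protocol[, "B"]),
              x$stress_fold, x$lowq_fraction, x$amplification_mean, x$seed))
  invisible(x)
}

# Gene rate matrix (genes x types) per protocol. Base rates and type
# multipliers are shared across protocols; stress genes are scaled in A only.
sim_rates <- function(spec) {
  with_seed_(child_seed(spec$seed, 11L), {
    base <- rlnorm(spec$n_genes, spec$base_rate_log_mean, spec$base_rate_log_sd)
    mult <- matrix(rlnorm(spec$n_genes * spec$n_cell_types, 0, spec$type_effect_sd),
                   spec$n_genes, spec$n_cell_types)
    rates <- base * mult
    rownames(rates) <- spec$gene_ids
    rates
  })
}

sim_gene_meta <- function(spec) {
  data.frame(gene_id = spec$gene_ids,
             biotype = ifelse(spec$gene_ids %in% spec$mt_gene_ids,
                              "protein_coding_mt", "protein_coding"),
             is_mito = spec$gene_ids %in% spec$mt_gene_ids,
             is_ribo = FALSE,
             is_stress = spec$gene_ids %in% spec$stress_gene_ids,
             stringsAsFactors = FALSE)
}

# Draw per-molecule (cell, gene) assignments for one protocol.
# Returns list(cell_idx, gene_idx, cell_type, totals).
sim_molecule_assignments <- function(spec, protocol, seed) {
  rates <- sim_rates(spec)
  if (protocol == "A") {
    idx <- match(spec$stress_gene_ids, spec$gene_ids)
    rates[idx, ] <- rates[idx, ] * spec$stress_fold
  }
  n_per_type <- spec$cells_per_type_per_protocol[, protocol]
  with_seed_(seed, {
    cell_type <- rep(seq_len(spec$n_cell_types), n_per_type)
    n_cells <- length(cell_type)
    totals <- pmax(1L, as.integer(round(rlnorm(n_cells,
                                               spec$library_size_log_mean,
                                               spec$library_size_log_sd))))
    gene_idx <- integer(sum(totals))
    cell_idx <- rep(seq_len(n_cells), totals)
    off <- 0L
    for (t in seq_len(spec$n_cell_types)) {
      in_t <- which(cell_type == t)
      if (!length(in_t)) next
      m <- sum(totals[in_t])
      gene_idx[off + seq_len(m)] <- sample.int(spec$n_genes, m, replace = TRUE,
                                               prob = rates[, t])
      off <- off + m
    }
    list(cell_idx = cell_idx, gene_idx = gene_idx,
         cell_type = cell_type, totals = totals)
  })
}

barcode_ids <- function(protocol, n) sprintf("%s-CELL%05d", protocol, seq_len(n))

#' Simulate a pair of protocol libraries at molecule level
#'
#' Draws one library per protocol from a [synthetic_spec()]: cell types from
#' the protocol's composition column, per-cell totals from the log-normal
#' library-size model, molecule gene identities from type-specific multinomial
#' rates (stress genes scaled by `stress_fold` in protocol A), and
#' per-molecule read counts from the shifted negative-binomial amplification
#' model. UMI tokens are unique within (barcode, gene) by construction. If
#' `lowq_fraction > 0`, that fraction of barcodes per library is degraded via
#' [plant_low_quality_cells()]. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `table_a`, `table_b` ([molecule_table()]s) and
#'   `truth` (data.frame: barcode, protocol, cell_type, low_quality).
#' @export
simulate_protocol_pair <- function(spec) {
  validate_synthetic_spec(spec)
  out <- list()
  truth <- list()
  for (p in c("A", "B")) {
    asg <- sim_molecule_assignments(spec, p, child_seed(spec$seed, if (p == "A") 21L else 22L))
    bcs <- barcode_ids(p, length(asg$cell_type))
    dt <- data.table::data.table(cell_barcode = bcs[asg$cell_idx],
                                 gene_id = spec$gene_ids[asg$gene_idx])
    dt[, umi := sprintf("U%06d", seq_len(.N)), by = c("cell_barcode", "gene_id")]
    nb_seed <- child_seed(spec$seed, if (p == "A") 31L else 32L)
    reads <- with_seed_(nb_seed,
      1L + rnbinom(nrow(dt), size = spec$amplification_dispersion,
                   mu = spec$amplification_mean - 1))
    tab <- molecule_table(dt$cell_barcode, dt$umi, dt$gene_id, reads,
                          library_id = paste0("protocol_", p))
    tr <- data.frame(barcode = bcs, protocol = p,
                     cell_type = paste0("type", asg$cell_type),
                     low_quality = FALSE, stringsAsFactors = FALSE)
    if (spec$lowq_fraction > 0) {
      lq <- plant_low_quality_cells(tab, spec,
                                    seed = child_seed(spec$seed, if (p == "A") 41L else 42L))
      tab <- lq$table
      tr$low_quality <- tr$barcode %in% lq$flagged
    }
    out[[p]] <- tab
    truth[[p]] <- tr
  }
  list(table_a = out$A, table_b = out$B,
       truth = rbind(truth$A, truth$B))
}

#' Simulate a pair of protocol libraries directly at count level
#'
#' Same generative model as [simulate_protocol_pair()] but skips molecule/read
#' expansion and returns a single UMI [count_matrix()] holding both protocols'
#' cells, with protocol, cell-type and low-quality ground truth in
#' `cell_meta`. Intended for downstream statistics (DE, signatures,
#' pseudo-bulk) where read-level structure is irrelevant and many replicate
#' draws are needed.
#'
#' @param spec a [synthetic_spec()].
#' @return A [count_matrix()] with `cell_meta` columns `protocol`,
#'   `cell_type`, `low_quality`.
#' @export
simulate_count_pair <- function(spec) {
  validate_synthetic_spec(spec)
  mats <- list(); metas <- list()
  for (p in c("A", "B")) {
    asg <- sim_molecule_assignments(spec, p, child_seed(spec$seed, if (p == "A") 21L else 22L))
    n_cells <- length(asg$cell_type)
    m <- Matrix::sparseMatrix(i = asg$gene_idx, j = asg$cell_idx,
                              x = rep(1, length(asg$gene_idx)),
                              dims = c(spec$n_genes, n_cells))
    meta <- data.frame(barcode = barcode_ids(p, n_cells), protocol = p,
                       cell_type = paste0("type", asg$cell_type),
                       low_quality = FALSE, stringsAsFactors = FALSE)
    if (spec$lowq_fraction > 0) {
      deg <- degrade_count_cells(m, spec, child_seed(spec$seed, if (p == "A") 41L else 42L))
      m <- deg$m
      meta$low_quality <- deg$flagged
    }
    mats[[p]] <- m; metas[[p]] <- meta
  }
  m <- cbind(mats$A, mats$B)
  meta <- rbind(metas$A, metas$B)
  rownames(m) <- spec$gene_ids
  colnames(m) <- meta$barcode
  count_matrix(m, cell_meta = meta, gene_meta = sim_gene_meta(spec))
}

# Count-level analogue of plant_low_quality_cells: operates on a genes x cells
# sparse matrix, returns the degraded matrix and a logical flag vector.
degrade_count_cells <- function(m, spec, seed) {
  n_cells <- ncol(m)
  n_flag <- round(spec$lowq_fraction * n_cells)
  flagged <- rep(FALSE, n_cells)
  if (n_flag == 0) return(list(m = m, flagged = flagged))
  mt_idx <- match(spec$mt_gene_ids, spec$gene_ids)
  with_seed_(seed, {
    pick <- sample.int(n_cells, n_flag)
    flagged[pick] <- TRUE
    totals <- Matrix::colSums(m)
    q05 <- quantile(totals[!flagged], 0.05, names = FALSE)
    lib_mt <- sum(m[mt_idx, , drop = FALSE]) / sum(m)
    for (j in pick) {
      col <- m[, j]
      new_total <- max(1L, as.integer(ceiling(0.5 * q05 * runif(1, 0.5, 1))))
      f <- sum(col[mt_idx]) / sum(col)
      f2 <- clamp(spec$lowq_mt_boost * max(f, lib_mt, 0.02), 0, 0.95)
      p_mt <- col[mt_idx]
      if (sum(p_mt) == 0) p_mt <- rep(1, length(mt_idx))
      p_rest <- col
      p_rest[mt_idx] <- 0
      prob <- p_rest / sum(p_rest) * (1 - f2)
      prob[mt_idx] <- p_mt / sum(p_mt) * f2
      m[, j] <- as.numeric(rmultinom(1, new_total, prob))
    }
    list(m = m, flagged = flagged)
  })
}

#' Degrade a fraction of barcodes into low-quality cells
#'
#' Re-assigns the molecules of a seeded random fraction of barcodes so that
#' the expected mitochondrial fraction is multiplied by `lowq_mt_boost`
#' (capped at 0.95) and the total UMI count falls below the 5th percentile of
#' the remaining cells. These are the barcodes the QC stage is expected to
#' remove.
#'
#' @param table a [molecule_table()].
#' @param spec a [synthetic_spec()] supplying `lowq_fraction`,
#'   `lowq_mt_boost` and `mt_gene_ids`.
#' @param seed RNG seed (defaults to a child of the spec seed).
#' @return List with the modified `table` and the `flagged` barcodes.
#' @export
plant_low_quality_cells <- function(table, spec, seed = child_seed(spec$seed, 41L)) {
  validate_synthetic_spec(spec)
  if (spec$lowq_fraction == 0) return(list(table = table, flagged = character()))
  bcs <- unique(table$cell_barcode)
  n_flag <- round(spec$lowq_fraction * length(bcs))
  if (n_flag == 0) return(list(table = table, flagged = character()))

  dt <- data.table::as.data.table(as.data.frame(table))
  with_seed_(seed, {
    flagged <- sample(bcs, n_flag)
    totals <- dt[, .N, by = "cell_barcode"]
    q05 <- quantile(totals$N[!totals$cell_barcode %in% flagged], 0.05, names = FALSE)
    is_mt <- dt$gene_id %in% spec$mt_gene_ids
    lib_mt <- mean(is_mt)
    keep <- dt[!dt$cell_barcode %in% flagged]
    new_rows <- lapply(flagged, function(bc) {
      cell <- dt[dt$cell_barcode == bc]
      mt_rows <- cell$gene_id %in% spec$mt_gene_ids
      f <- mean(mt_rows)
      f2 <- clamp(spec$lowq_mt_boost * max(f, lib_mt, 0.02), 0, 0.95)
      new_total <- max(1L, as.integer(ceiling(0.5 * q05 * runif(1, 0.5, 1))))
      n_mt <- rbinom(1, new_total, f2)
      mt_genes <- if (any(mt_rows)) sample(cell$gene_id[mt_rows], n_mt, replace = TRUE)
                  else sample(spec$mt_gene_ids, n_mt, replace = TRUE)
      other_pool <- if (any(!mt_rows)) cell$gene_id[!mt_rows] else setdiff(spec$gene_ids, spec$mt_gene_ids)
      other_genes <- sample(other_pool, new_total - n_mt, replace = TRUE)
      g <- c(mt_genes, other_genes)
      out <- data.table::data.table(cell_barcode = bc, gene_id = g)
      out[, umi := sprintf("LQ%06d", seq_len(.N)), by = "gene_id"]
      out$read_count <- 1L + rnbinom(nrow(out), size = spec$amplification_dispersion,
                                     mu = spec$amplification_mean - 1)
      out[, c("cell_barcode", "umi", "gene_id", "read_count")]
    })
    res <- data.table::rbindlist(c(list(keep[, c("cell_barcode", "umi", "gene_id", "read_count")]),
                                   new_rows))
    list(table = molecule_table(res$cell_barcode, res$umi, res$gene_id,
                                res$read_count,
                                library_id = attr(table, "library_id") %||% "library"),
         flagged = flagged)
  })
}

#' Write a simulated pair to disk
#'
#' Persists the two molecule tables, the collapsed count matrices (Matrix
#' Market + sidecars), the truth labels and the spec parameters, so that
#' individual pipeline stages can be re-run from files.
#'
#' @param sim result of [simulate_protocol_pair()].
#' @param spec the generating [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_molecule_table(sim$table_a, file.path(dir, "molecules_A.tsv"))
  write_molecule_table(sim$table_b, file.path(dir, "molecules_B.tsv"))
  gm <- sim_gene_meta(spec)
  write_mtx(collapse_to_matrix(sim$table_a, gene_meta = gm), file.path(dir, "counts_A"))
  write_mtx(collapse_to_matrix(sim$table_b, gene_meta = gm), file.path(dir, "counts_B"))
  data.table::fwrite(sim$truth, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE)
  cfg <- spec[setdiff(names(spec), c("gene_ids"))]
  cfg$cells_per_type_per_protocol <- as.data.frame(cfg$cells_per_type_per_protocol)
  yaml::write_yaml(cfg, file.path(dir, "synthetic_spec.yaml"))
  invisible(dir)
}
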