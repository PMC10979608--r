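#' Per-cell quality-control metrics
#'
#' Library size (total UMIs), library complexity (genes with nonzero count),
#' and the percentage of counts on mitochondrial and ribosomal genes, per
#' barcode. Cells with zero counts get `NA` percentages and are flagged in
#' the `undefined_pct` column rather than dropped — filtering is a separate
#' decision.
#'
#' @param matrix a [count_matrix()] whose `gene_meta` carries `is_mito` and
#'   `is_ribo`.
#' @return Data.frame with one row per barcode: `barcode`, `n_umi`, `n_gene`,
#'   `pct_mt`, `pct_ribo`, `undefined_pct`.
#' @export
compute_qc <- function(matrix) {
  gm <- matrix$gene_meta
  if (!all(c("is_mito", "is_ribo") %in% names(gm)))
    stopf("gene_meta must contain is_mito and is_ribo flags")
  m <- matrix$counts
  n_umi <- Matrix::colSums(m)
  n_gene <- Matrix::colSums(m > 0)
  mt <- Matrix::colSums(m[gm$is_mito, , drop = FALSE])
  rb <- Matrix::colSums(m[gm$is_ribo, , drop = FALSE])
  pct_mt <- ifelse(n_umi > 0, 100 * mt / n_umi, NA_real_)
  pct_ribo <- ifelse(n_umi > 0, 100 * rb / n_umi, NA_real_)
  data.frame(barcode = colnames(m), n_umi = as.integer(n_umi),
             n_gene = as.integer(n_gene), pct_mt = pct_mt,
             pct_ribo = pct_ribo, undefined_pct = n_umi == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' QC filtering thresholds
#'
#' Bounds on per-cell metrics, optionally with the two-pass mitochondrial
#' scheme used for colon tissue: a permissive first pass on MT%, then
#' lineage-specific MT% ceilings applied to the survivors (epithelial cells
#' tolerate a higher mitochondrial load than non-epithelial ones). All bounds
#' are optional; an unset bound filters nothing. Presets carry the published
#' colon cutoffs: `"mouse_colon"` = pass 1 at 75% MT, then 60% (epithelial) /
#' 50% (non-epithelial); `"human_colon"` = 85%, then 60% / 25%.
#'
#' @param min_umi,max_umi,min_gene,max_gene bounds on library size/complexity.
#' @param max_pct_mt single-pass MT% ceiling.
#' @param two_pass optional list: `pass1_max_pct_mt` plus `lineage_max_pct_mt`
#'   (named numeric, lineage -> MT% ceiling).
#' @param preset `"mouse_colon"` or `"human_colon"`; overrides `two_pass`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = NULL, max_umi = NULL,
                          min_gene = NULL, max_gene = NULL,
                          max_pct_mt = NULL, two_pass = NULL,
                          preset = NULL) {
  if (!is.null(preset)) {
    two_pass <- switch(match.arg(preset, c("mouse_colon", "human_colon")),
      mouse_colon = list(pass1_max_pct_mt = 75,
                         lineage_max_pct_mt = c(epithelial = 60, non_epithelial = 50)),
      human_colon = list(pass1_max_pct_mt = 85,
                         lineage_max_pct_mt = c(epithelial = 60, non_epithelial = 25)))
  }
  for (pair in list(c(min_umi, max_umi), c(min_gene, max_gene)))
    if (length(pair) == 2 && pair[1] > pair[2])
      stopf("min threshold exceeds max threshold")
  structure(list(min_umi = min_umi, max_umi = max_umi, min_gene = min_gene,
                 max_gene = max_gene, max_pct_mt = max_pct_mt,
                 two_pass = two_pass), class = "qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' Single-pass mode keeps cells inside all configured bounds. Two-pass mode
#' first removes cells above the permissive MT% bound, then applies each
#' surviving cell's lineage-specific MT% ceiling; lineage labels are required
#' for every pass-1 survivor. Cells with undefined percentages (zero counts)
#' are always removed when any MT bound is set.
#'
#' @param matrix a [count_matrix()] (used for barcode order).
#' @param metrics output of [compute_qc()].
#' @param thresholds a [qc_thresholds()].
#' @param lineage_labels named character vector (barcode -> lineage), needed
#'   in two-pass mode.
#' @return List: `kept` (character barcodes) and `tally` (named removal
#'   counts per rule; sums to n_input - n_kept).
#' @export
filter_cells <- function(matrix, metrics, thresholds, lineage_labels = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  bc <- metrics$barcode
  alive <- rep(TRUE, length(bc))
  tally <- c()
  drop_rule <- function(alive, bad, rule) {
    bad <- bad & alive
    tally[rule] <<- sum(bad)
    alive & !bad
  }
  th <- thresholds
  if (!is.null(th$min_umi)) alive <- drop_rule(alive, metrics$n_umi < th$min_umi, "min_umi")
  if (!is.null(th$max_umi)) alive <- drop_rule(alive, metrics$n_umi > th$max_umi, "max_umi")
  if (!is.null(th$min_gene)) alive <- drop_rule(alive, metrics$n_gene < th$min_gene, "min_gene")
  if (!is.null(th$max_gene)) alive <- drop_rule(alive, metrics$n_gene > th$max_gene, "max_gene")
  pct <- metrics$pct_mt
  if (!is.null(th$max_pct_mt))
    alive <- drop_rule(alive, is.na(pct) | pct > th$max_pct_mt, "max_pct_mt")
  if (!is.null(th$two_pass)) {
    tp <- th$two_pass
    alive <- drop_rule(alive, is.na(pct) | pct > tp$pass1_max_pct_mt, "pass1_max_pct_mt")
    if (any(alive)) {
      if (is.null(lineage_labels)) stopf("two-pass filtering requires lineage_labels")
      lin <- lineage_labels[bc]
      missing_lin <- alive & (is.na(lin) | !(lin %in% names(tp$lineage_max_pct_mt)))
      if (any(missing_lin))
        stopf("no lineage label (or no threshold) for surviving barcode %s",
              bc[which(missing_lin)[1]])
      bound <- tp$lineage_max_pct_mt[lin]
      alive <- drop_rule(alive, !is.na(bound) & pct > bound, "pass2_lineage_max_pct_mt")
    }
  }
  list(kept = bc[alive], tally = tally)
}

#' Remove genes detected in too few cells
#'
#' @param matrix a [count_matrix()].
#' @param min_cells keep genes with nonzero counts in at least this many
#'   cells (0 keeps everything).
#' @return A [count_matrix()] with the surviving genes.
#' @export
filter_genes <- function(matrix, min_cells = 3) {
  if (min_cells < 0) stopf("min_cells must be >= 0")
  keep <- Matrix::rowSums(matrix$counts > 0) >= min_cells
  subset_cm(matrix, i = which(keep))
}

#' Depth-normalize and log-transform counts
#'
#' Each entry becomes `ln(1 + scale * count / cell_total)` — counts scaled to
#' a common per-cell total, then shifted-log transformed. Zeros stay zero, so
#' sparsity is preserved.
#'
#' @param matrix a [count_matrix()]; cells with zero counts must already be
#'   filtered out.
#' @param scale target per-cell total (default 1e4).
#' @return The `count_matrix` with a real-valued `counts` slot and attribute
#'   `normalized = TRUE` on the object.
#' @export
normalize_log <- function(matrix, scale = 1e4) {
  totals <- Matrix::colSums(matrix$counts)
  if (any(totals == 0)) stopf("all-zero cell present; filter cells first")
  m <- matrix$counts
  m@x <- log1p(scale * m@x / rep.int(totals, diff(m@p)))
  matrix$counts <- m
  matrix$normalized <- TRUE
  matrix
}

#' Rank genes by standardized variance (vst-style HVG selection)
#'
#' Fits a loess trend of log10 variance on log10 mean over the raw counts,
#' predicts each gene's expected standard deviation from the trend,
#' standardizes counts with those expected sds, clips standardized values at
#' `sqrt(n_cells)`, and ranks genes by the variance of the clipped values.
#' Ties are broken by gene id, making the ranking fully deterministic.
#'
#' @param matrix a [count_matrix()] of raw counts.
#' @param n_top number of genes to report (default 2000; capped at the number
#'   of genes with positive variance).
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return Character vector of gene ids, most variable first, with attribute
#'   `standardized_variance` (the full named score vector).
#' @export
select_hvgs <- function(matrix, n_top = 2000, loess_span = 0.3) {
  m <- matrix$counts
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  ok <- v > 0 & mu > 0
  if (!any(ok)) stopf("no variable genes (constant matrix)")
  sd_exp <- rep(NA_real_, length(mu))
  if (sum(ok) >= 10) {
    span <- max(loess_span, min(1, 30 / sum(ok)))  # widen on tiny gene counts
    fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = span,
                 degree = 2, family = "gaussian")
    sd_exp[ok] <- sqrt(10^predict(fit, log10(mu[ok])))
  } else {
    sd_exp[ok] <- sqrt(v[ok])  # too few variable genes for a trend fit
  }
  clip <- sqrt(n)
  # variance of clipped standardized values, computed sparsely:
  # zeros standardize to -mu/sd (clip cannot trigger there for count data).
  std_var <- rep(0, length(mu))
  names(std_var) <- rownames(m)
  cm <- methods::as(m, "TsparseMatrix")
  z_nz <- pmin((cm@x - mu[cm@i + 1L]) / sd_exp[cm@i + 1L], clip)
  z0 <- -mu / sd_exp
  n_nz <- tabulate(cm@i + 1L, nbins = length(mu))
  sum_z <- z0 * (n - n_nz) + tapply_sum(z_nz, cm@i + 1L, length(mu))
  sum_z2 <- z0^2 * (n - n_nz) + tapply_sum(z_nz^2, cm@i + 1L, length(mu))
  std_var[ok] <- ((sum_z2 - sum_z^2 / n) / (n - 1))[ok]
  ord <- order(-std_var, names(std_var))
  ranked <- names(std_var)[ord]
  out <- head(ranked, n_top)
  attr(out, "standardized_variance") <- std_var[ord]
  out
}

tapply_sum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Fraction of shared top highly-variable genes
#'
#' @param list_a,list_b ranked gene lists (most variable first).
#' @param n number of top genes compared (default 2000).
#' @return `|top-n(a) intersect top-n(b)| / n`, in `[0, 1]`.
#' @export
hvg_overlap <- function(list_a, list_b, n = 2000) {
  if (length(list_a) < n || length(list_b) < n)
    stopf("both lists must have at least n = %d genes", n)
  length(intersect(head(list_a, n), head(list_b, n))) / n
}
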