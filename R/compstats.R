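#' Pseudo-bulk expression profile
#'
#' Per-gene mean of the log-normalized expression over a set of cells — the
#' pseudo-bulk convention that lets two single-cell conditions be compared
#' like bulk samples.
#'
#' @param norm_matrix a log-normalized [count_matrix()] (see
#'   [normalize_log()]).
#' @param cell_subset barcodes or column indices; must be nonempty.
#' @return Named numeric vector, one value per gene.
#' @export
pseudobulk_profile <- function(norm_matrix, cell_subset) {
  if (length(cell_subset) == 0) stopf("empty cell subset")
  m <- norm_matrix$counts[, cell_subset, drop = FALSE]
  Matrix::rowMeans(m)
}

#' Pseudo-bulk Pearson correlation between two protocols
#'
#' Computes the squared Pearson correlation between the two protocols'
#' pseudo-bulk profiles, globally and per cell type. Population-size rules:
#' a cell type is compared only if it has more than `min_total` cells overall
#' and more than `min_per_cond` in each protocol; to avoid size-driven bias
#' the larger condition is subsampled without replacement to the smaller's
#' size before profiling. Correlation is computed over genes expressed
#' (nonzero mean) in either profile; significance comes from the t-test of
#' the correlation coefficient, and a comparison is flagged `passed_strong`
#' when r^2 > 0.9 and p < 0.05.
#'
#' @param norm_matrix log-normalized [count_matrix()].
#' @param protocol_labels per-cell protocol (exactly two levels), recycled
#'   from `cell_meta$protocol` when `NULL`.
#' @param cell_type_labels optional per-cell types for per-type results.
#' @param min_total minimum cells of a type across both protocols (default 100).
#' @param min_per_cond minimum cells of a type per protocol (default 20).
#' @param downsample subsample the larger condition to the smaller (default
#'   TRUE).
#' @param seed RNG seed for the subsampling.
#' @return Data.frame of `correlation_result` rows: scope, r_squared,
#'   p_value, n_a, n_b, passed_strong, skipped, reason.
#' @export
pseudobulk_correlation <- function(norm_matrix, protocol_labels = NULL,
                                   cell_type_labels = NULL,
                                   min_total = 100, min_per_cond = 20,
                                   downsample = TRUE, seed = NULL) {
  protocol_labels <- protocol_labels %||% norm_matrix$cell_meta$protocol
  prots <- sort(unique(protocol_labels))
  if (length(prots) != 2)
    stopf("need exactly two protocols, got: %s", paste(prots, collapse = ", "))
  idx_a <- which(protocol_labels == prots[1])
  idx_b <- which(protocol_labels == prots[2])
  if (!length(idx_a) || !length(idx_b)) stopf("a protocol has no cells")

  one_scope <- function(scope, ia, ib, k) {
    n <- min(length(ia), length(ib))
    if (downsample) {
      sub <- with_seed_(child_seed(seed, 300L + k), list(
        a = if (length(ia) > n) sample(ia, n) else ia,
        b = if (length(ib) > n) sample(ib, n) else ib))
      ia <- sub$a; ib <- sub$b
    }
    pa <- pseudobulk_profile(norm_matrix, ia)
    pb <- pseudobulk_profile(norm_matrix, ib)
    expressed <- pa > 0 | pb > 0
    ct <- cor.test(pa[expressed], pb[expressed], method = "pearson")
    r2 <- unname(ct$estimate)^2
    data.frame(scope = scope, r_squared = r2, p_value = ct$p.value,
               n_a = length(ia), n_b = length(ib),
               passed_strong = r2 > 0.9 & ct$p.value < 0.05,
               skipped = FALSE, reason = "", stringsAsFactors = FALSE)
  }
  res <- list(one_scope("global", idx_a, idx_b, 0L))
  if (!is.null(cell_type_labels)) {
    for (k in seq_along(tys <- sort(unique(cell_type_labels)))) {
      ty <- tys[k]
      ia <- idx_a[cell_type_labels[idx_a] == ty]
      ib <- idx_b[cell_type_labels[idx_b] == ty]
      skip_reason <-
        if (length(ia) + length(ib) <= min_total) "min_total"
        else if (min(length(ia), length(ib)) <= min_per_cond) "min_per_cond"
        else ""
      res[[length(res) + 1]] <- if (nzchar(skip_reason)) {
        data.frame(scope = ty, r_squared = NA_real_, p_value = NA_real_,
                   n_a = length(ia), n_b = length(ib), passed_strong = NA,
                   skipped = TRUE, reason = skip_reason, stringsAsFactors = FALSE)
      } else one_scope(ty, ia, ib, k)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Descriptive cell-type composition comparison
#'
#' Per-protocol cell-type proportions, the log2 ratio of proportions
#' (protocol A over B, with a 0.5 pseudo-count on zero cell counts), and a
#' percentile bootstrap 95% CI of the ratio obtained by resampling cells
#' within each protocol. This is a descriptive summary, not a compositional
#' model: CIs quantify sampling variability of the observed proportions only.
#'
#' @param cell_type_labels,protocol_labels per-cell vectors (two protocols).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return Data.frame: cell_type, prop_a, prop_b, log2_ratio, ci_low,
#'   ci_high, n_a, n_b.
#' @export
composition_compare <- function(cell_type_labels, protocol_labels,
                                n_boot = 1000, seed = NULL) {
  prots <- sort(unique(protocol_labels))
  if (length(prots) != 2) stopf("need exactly two protocols")
  a <- cell_type_labels[protocol_labels == prots[1]]
  b <- cell_type_labels[protocol_labels == prots[2]]
  types <- sort(unique(cell_type_labels))
  count_of <- function(x) {
    tab <- table(factor(x, levels = types))
    as.numeric(tab)
  }
  ratio_of <- function(ca, cb) {
    ca2 <- ifelse(ca == 0, 0.5, ca); cb2 <- ifelse(cb == 0, 0.5, cb)
    log2((ca2 / sum(ca2)) / (cb2 / sum(cb2)))
  }
  ca <- count_of(a); cb <- count_of(b)
  obs <- ratio_of(ca, cb)
  boots <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(i)
      ratio_of(count_of(sample(a, replace = TRUE)),
               count_of(sample(b, replace = TRUE))),
      numeric(length(types)))
  })
  boots <- base::matrix(boots, nrow = length(types))
  ci <- apply(boots, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(cell_type = types,
             prop_a = ca / sum(ca), prop_b = cb / sum(cb),
             log2_ratio = obs, ci_low = ci[1, ], ci_high = ci[2, ],
             n_a = ca, n_b = cb, stringsAsFactors = FALSE)
}

#' Rank-sum differential expression with fold-change, FDR and presence filters
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized expression
#' between two protocols. Genes present in fewer than `min_pct` of cells in
#' both groups are excluded before testing. The log2 fold change is computed
#' on de-logged means: `log2((mean(expm1(norm)) in A + eps) / (same in B +
#' eps))` with `eps = 1 / mean(group size)`. P-values are BH-adjusted over
#' the tested genes, and a gene is flagged significant when |log2FC| > 1,
#' adjusted p < 0.05 and it is present in at least `min_pct` of cells.
#'
#' @param norm_matrix log-normalized [count_matrix()].
#' @param protocol_labels per-cell protocol (two levels, each >= 3 cells);
#'   taken from `cell_meta$protocol` when `NULL`.
#' @param min_pct presence filter (default 0.10).
#' @param logfc_min fold-change filter on |log2FC| (default 1).
#' @param alpha FDR level (default 0.05).
#' @return Data.frame (`de_result`): gene_id, log2fc, pct_a, pct_b, p_value,
#'   p_adj, tested, significant. Direction: positive log2fc = higher in the
#'   first (alphabetical) protocol.
#' @export
differential_expression <- function(norm_matrix, protocol_labels = NULL,
                                    min_pct = 0.10, logfc_min = 1,
                                    alpha = 0.05) {
  protocol_labels <- protocol_labels %||% norm_matrix$cell_meta$protocol
  prots <- sort(unique(protocol_labels))
  if (length(prots) != 2) stopf("need exactly two protocols")
  ia <- which(protocol_labels == prots[1])
  ib <- which(protocol_labels == prots[2])
  if (length(ia) < 3 || length(ib) < 3) stopf("each group needs >= 3 cells")
  m <- norm_matrix$counts
  ma <- m[, ia, drop = FALSE]; mb <- m[, ib, drop = FALSE]
  pct_a <- Matrix::rowSums(ma > 0) / length(ia)
  pct_b <- Matrix::rowSums(mb > 0) / length(ib)
  eps <- 1 / mean(c(length(ia), length(ib)))
  mean_a <- Matrix::rowMeans(expm1(ma))
  mean_b <- Matrix::rowMeans(expm1(mb))
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  tested <- pmax(pct_a, pct_b) >= min_pct
  p <- rep(NA_real_, nrow(m))
  da <- as.matrix(ma[tested, , drop = FALSE])
  db <- as.matrix(mb[tested, , drop = FALSE])
  p[tested] <- vapply(seq_len(nrow(da)), function(g)
    suppressWarnings(wilcox.test(da[g, ], db[g, ], exact = FALSE)$p.value),
    numeric(1))
  p_adj <- rep(NA_real_, nrow(m))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  sig <- tested & !is.na(p_adj) & abs(log2fc) > logfc_min & p_adj < alpha &
         pmax(pct_a, pct_b) >= min_pct
  out <- data.frame(gene_id = rownames(m), log2fc = log2fc,
                    pct_a = pct_a, pct_b = pct_b, p_value = p, p_adj = p_adj,
                    tested = tested, significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- prots
  attr(out, "test") <- "wilcoxon_rank_sum"   # rank-sum substitute for a hurdle model
  class(out) <- c("de_result", "data.frame")
  out
}

#' Biotype breakdown of shared and protocol-unique genes
#'
#' Splits two libraries' detected gene lists into shared, unique-to-A and
#' unique-to-B sets and reports the biotype composition of each set.
#'
#' @param genes_a,genes_b character vectors of detected gene ids.
#' @param biotype_map named character vector (gene id -> biotype); genes
#'   without an entry are reported as `"unannotated"`.
#' @return List with `counts` (shared/unique_a/unique_b sizes) and
#'   `fractions` (per-set biotype fraction tables, each summing to 1).
#' @export
gene_category_breakdown <- function(genes_a, genes_b, biotype_map) {
  sets <- list(shared = intersect(genes_a, genes_b),
               unique_a = setdiff(genes_a, genes_b),
               unique_b = setdiff(genes_b, genes_a))
  frac <- lapply(sets, function(g) {
    if (!length(g)) return(numeric(0))
    bt <- biotype_map[g]
    bt[is.na(bt)] <- "unannotated"
    tab <- table(bt)
    setNames(as.numeric(tab) / length(g), names(tab))
  })
  list(counts = vapply(sets, length, integer(1)), fractions = frac,
       genes = sets)
}
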