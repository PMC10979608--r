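#' Rank-based per-cell gene-signature score
#'
#' Mann–Whitney-U–derived score of a gene set within each cell, bounded in
#' \[0, 1\]. Within a cell, genes are ranked by decreasing expression with
#' average ranks on ties; ranks beyond `r_max`, zero-expression genes and
#' signature genes absent from the matrix are all set to the ceiling
#' `r_max + 1`. With `U = sum(rank(g), g in S) - n_s(n_s+1)/2`, the score is
#' `clamp(1 - U / (n_s * r_max), 0, 1)`: 1 when the signature occupies the
#' top ranks, ~0 when it is unexpressed. The score depends only on
#' within-cell expression ranks, so it is invariant under any monotone
#' transform of the expression values.
#'
#' @param norm_matrix a (typically log-normalized) [count_matrix()].
#' @param signature character vector of gene ids (nonempty; genes absent from
#'   the matrix contribute the ceiling rank).
#' @param r_max rank ceiling (default 1500; must be < number of genes).
#' @param signature_name label attached to the result.
#' @return Data.frame (`signature_scores`): barcode, score; attributes
#'   `signature_name`, `n_signature_genes`, `r_max`.
#' @export
score_signature <- function(norm_matrix, signature, r_max = 1500,
                            signature_name = "signature") {
  if (length(signature) == 0) stopf("empty signature")
  m <- norm_matrix$counts
  if (r_max >= nrow(m))
    stopf("r_max (%d) must be smaller than the gene count (%d)", r_max, nrow(m))
  n_s <- length(signature)
  sig_idx <- match(signature, rownames(m))
  ceiling_rank <- r_max + 1
  ptr <- m@p
  scores <- vapply(seq_len(ncol(m)), function(j) {
    nz <- if (ptr[j + 1] > ptr[j]) (ptr[j] + 1):ptr[j + 1] else integer()
    genes_nz <- m@i[nz] + 1L
    vals <- m@x[nz]
    pos <- vals > 0
    genes_nz <- genes_nz[pos]; vals <- vals[pos]
    r <- rank(-vals, ties.method = "average")
    r[r > r_max] <- ceiling_rank
    rk <- rep(ceiling_rank, n_s)
    hit <- match(sig_idx, genes_nz)
    found <- !is.na(hit)
    rk[found] <- r[hit[found]]
    u <- sum(rk) - n_s * (n_s + 1) / 2
    clamp(1 - u / (n_s * r_max), 0, 1)
  }, numeric(1))
  out <- data.frame(barcode = colnames(m), score = scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "signature_name") <- signature_name
  attr(out, "n_signature_genes") <- n_s
  attr(out, "r_max") <- r_max
  class(out) <- c("signature_scores", "data.frame")
  out
}

#' Compare signature scores between protocols
#'
#' Within each cell type (and globally), caps cells at `max_cells_per_type`
#' per protocol by seeded subsampling — protecting the test from unequal
#' population sizes — and runs a two-sided Wilcoxon rank-sum test on the
#' per-cell scores between the two protocols. Strata missing a protocol are
#' reported as skipped.
#'
#' @param scores a [score_signature()] result.
#' @param protocol_labels,cell_type_labels per-cell vectors aligned with
#'   `scores$barcode`.
#' @param max_cells_per_type cap per (type, protocol) (default 250).
#' @param seed RNG seed for the subsampling.
#' @param paired use the signed-rank test on explicitly paired cells (both
#'   groups must then be equal-length and ordered); default FALSE (unpaired
#'   protocol groups, rank-sum test).
#' @return Data.frame: scope, p_value, median_diff (A - B medians), n_a,
#'   n_b, skipped, reason.
#' @export
compare_scores <- function(scores, protocol_labels, cell_type_labels = NULL,
                           max_cells_per_type = 250, seed = NULL,
                           paired = FALSE) {
  prots <- sort(unique(protocol_labels))
  if (length(prots) != 2) stopf("need exactly two protocols")
  strata <- list(global = rep(TRUE, nrow(scores)))
  if (!is.null(cell_type_labels)) {
    tys <- sort(unique(cell_type_labels))
    strata <- c(strata, setNames(lapply(tys, function(t) cell_type_labels == t), tys))
  }
  rows <- lapply(seq_along(strata), function(k) {
    in_s <- strata[[k]]
    scope <- names(strata)[k]
    sa <- scores$score[in_s & protocol_labels == prots[1]]
    sb <- scores$score[in_s & protocol_labels == prots[2]]
    if (!length(sa) || !length(sb))
      return(data.frame(scope = scope, p_value = NA_real_,
                        median_diff = NA_real_, n_a = length(sa),
                        n_b = length(sb), skipped = TRUE,
                        reason = "protocol absent", stringsAsFactors = FALSE))
    cap <- max_cells_per_type
    sub <- with_seed_(child_seed(seed, 400L + k), list(
      a = if (length(sa) > cap) sample(sa, cap) else sa,
      b = if (length(sb) > cap) sample(sb, cap) else sb))
    wt <- suppressWarnings(wilcox.test(sub$a, sub$b, exact = FALSE,
                                       paired = paired))
    data.frame(scope = scope, p_value = wt$p.value,
               median_diff = median(sub$a) - median(sub$b),
               n_a = length(sub$a), n_b = length(sub$b),
               skipped = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
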