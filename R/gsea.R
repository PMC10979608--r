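#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov–Smirnov-style statistic of pre-ranked gene-set
#' enrichment: walking down the ranked list, set members ("hits") increment
#' the running sum by `|stat|^p_weight / sum_hits |stat|^p_weight` and
#' non-members decrement it by `1 / (N - n_hits)`; the enrichment score is
#' the signed extremum of the running sum, in \[-1, 1\].
#'
#' @param ranked_stats named numeric vector of per-gene statistics; sorted
#'   decreasing internally (ties broken by gene id) so ranking is
#'   deterministic. Gene names must be unique.
#' @param gene_set character vector; must intersect the ranked list.
#' @param p_weight weighting exponent (default 1; 0 = classic unweighted KS).
#' @return The enrichment score (single numeric).
#' @export
enrichment_score <- function(ranked_stats, gene_set, p_weight = 1) {
  if (anyDuplicated(names(ranked_stats))) stopf("duplicate gene names in ranked list")
  ord <- order(-ranked_stats, names(ranked_stats))
  s <- ranked_stats[ord]
  pos <- sort(match(unique(gene_set), names(s)))
  pos <- pos[!is.na(pos)]
  if (!length(pos)) stopf("gene set does not intersect the ranked list")
  es_at_positions(pos, abs(s)^p_weight, length(s))
}

# ES from hit positions. Extrema of the running sum occur only at a hit
# (just after the increment) or just before a hit, so O(k) suffices.
es_at_positions <- function(pos, w_all, n) {
  k <- length(pos)
  if (k == n) return(1)      # degenerate: no misses, sum climbs to 1
  w <- w_all[pos]
  W <- sum(w)
  if (W == 0) w <- rep(1, k) else w <- w / W
  q <- 1 / (n - k)
  cum <- cumsum(w)
  at_hit <- cum - (pos - seq_len(k)) * q
  before_hit <- c(0, cum[-k]) - (pos - seq_len(k)) * q
  mx <- max(at_hit, before_hit)
  mn <- min(at_hit, before_hit)
  if (mx >= -mn) mx else mn                 # tie in |.|: prefer positive
}

#' Pre-ranked gene-set enrichment with a gene-permutation null
#'
#' Filters gene sets to those whose in-universe size lies within
#' `[min_size, max_size]`, computes each retained set's enrichment score on
#' the ranked statistics, and builds a per-set null by drawing `n_perm`
#' random gene sets of the same size from the ranked universe. The p-value
#' compares the observed score against null scores of the same sign
#' (`p = (1 + #{matching-sign null with |null| >= |es|}) / (1 + #matching)`),
#' the normalized score divides by the mean |null| of matching sign, and BH
#' adjustment runs over the retained sets. A set is flagged significant when
#' the adjusted p-value is < 0.05, more than 5 of its genes are in the
#' ranked universe, and those account for more than 15% of the set.
#'
#' @param ranked_stats named numeric vector (see [enrichment_score()]).
#' @param gene_sets named list of character vectors.
#' @param min_size,max_size in-universe size bounds (defaults 10 and 300).
#' @param n_perm permutations per set (default 1000).
#' @param p_weight weighting exponent (default 1).
#' @param seed RNG seed.
#' @return Data.frame (`gsea_result`): set, set_size, n_overlap,
#'   overlap_fraction, es, nes, p_value, p_adj, significant, excluded,
#'   reason. Deterministic given the seed.
#' @export
preranked_gsea <- function(ranked_stats, gene_sets, min_size = 10,
                           max_size = 300, n_perm = 1000, p_weight = 1,
                           seed = NULL) {
  ord <- order(-ranked_stats, names(ranked_stats))
  s <- ranked_stats[ord]
  n <- length(s)
  if (n < max_size) stopf("ranked list (%d genes) shorter than max_size", n)
  w_all <- abs(s)^p_weight
  info <- lapply(gene_sets, function(g) {
    g <- unique(g)
    pos <- sort(match(g, names(s)))
    list(size = length(g), pos = pos[!is.na(pos)])
  })
  rows <- with_seed_(seed, lapply(seq_along(info), function(k) {
    inf <- info[[k]]
    n_ov <- length(inf$pos)
    base <- data.frame(set = names(gene_sets)[k], set_size = inf$size,
                       n_overlap = n_ov,
                       overlap_fraction = if (inf$size) n_ov / inf$size else 0,
                       es = NA_real_, nes = NA_real_, p_value = NA_real_,
                       p_adj = NA_real_, significant = NA, excluded = TRUE,
                       reason = "size", stringsAsFactors = FALSE)
    if (n_ov < min_size || n_ov > max_size) return(base)
    es <- es_at_positions(inf$pos, w_all, n)
    null_es <- vapply(seq_len(n_perm), function(i)
      es_at_positions(sort.int(sample.int(n, n_ov)), w_all, n), numeric(1))
    same <- sign(null_es) == sign(es) & null_es != 0
    p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + sum(same))
    nes <- if (any(same)) es / mean(abs(null_es[same])) else NA_real_
    base$es <- es; base$nes <- nes; base$p_value <- p
    base$excluded <- FALSE; base$reason <- ""
    base
  }))
  out <- do.call(rbind, rows)
  tested <- !out$excluded
  if (!any(tested)) message("no gene sets survive the size filter")
  out$p_adj[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$significant[tested] <- out$p_adj[tested] < 0.05 &
    out$n_overlap[tested] > 5 & out$overlap_fraction[tested] > 0.15
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Ranking statistic from a differential-expression table
#'
#' `signed -log10(p) * sign(log2fc)` over the tested genes — the usual way to
#' feed a DE result into pre-ranked enrichment. Ties are broken by gene id
#' through the deterministic sort in [enrichment_score()].
#'
#' @param de a [differential_expression()] result.
#' @return Named numeric vector over tested genes.
#' @export
de_rank_statistic <- function(de) {
  keep <- de$tested & !is.na(de$p_value)
  p <- pmax(de$p_value[keep], 1e-300)
  setNames(-log10(p) * sign(de$log2fc[keep]), de$gene_id[keep])
}
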