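#' Equalize effective sequencing depth across libraries
#'
#' Brings all libraries to the same mean reads per barcode — the aggregation
#' convention of droplet pipelines, which subsample deeper libraries so every
#' library has the same average number of reads per cell. The shallowest
#' library (lowest mean reads per barcode) anchors the target and is returned
#' unchanged; every other library is downsampled without replacement
#' ([downsample_reads()]) to `round(target_mean * n_barcodes)` reads, which
#' matches the target mean to well within 1%.
#'
#' @param tables list of >= 2 [molecule_table()]s.
#' @param seed RNG seed; each downsampled library uses a child seed.
#' @return List of molecule tables in the input order.
#' @export
equalize_depth <- function(tables, seed = NULL) {
  if (length(tables) < 2) stopf("equalize_depth needs >= 2 libraries")
  means <- vapply(tables, function(t) {
    validate_molecule_table(t)
    total_reads(t) / length(unique(t$cell_barcode))
  }, numeric(1))
  target <- min(means)
  lapply(seq_along(tables), function(i) {
    if (means[i] <= target) return(tables[[i]])
    n_bc <- length(unique(tables[[i]]$cell_barcode))
    downsample_reads(tables[[i]], round(target * n_bc),
                     seed = child_seed(seed, 200L + i))
  })
}
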