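# Shared fixtures, built in code.

# Three molecules with reads (3, 2, 1) in one cell: the downsampler's
# exhaustive-enumeration instance.
tiny_table <- function() {
  molecule_table(cell_barcode = c("bc1", "bc1", "bc1"),
                 umi = c("u1", "u2", "u3"),
                 gene_id = c("gA", "gA", "gB"),
                 read_count = c(3L, 2L, 1L),
                 library_id = "tiny")
}

# Small count matrix from explicit per-cell gene sets (all counts 1).
matrix_from_gene_sets <- function(sets, genes = sort(unique(unlist(sets)))) {
  m <- vapply(sets, function(s) as.numeric(genes %in% s), numeric(length(genes)))
  m <- Matrix::Matrix(matrix(m, nrow = length(genes)), sparse = TRUE)
  rownames(m) <- genes
  colnames(m) <- paste0("cell", seq_along(sets))
  count_matrix(m)
}

# One-cell matrix with prescribed expression values, for score closed forms.
score_fixture <- function(values, genes = sprintf("g%03d", seq_along(values))) {
  m <- Matrix::Matrix(matrix(values, ncol = 1,
                             dimnames = list(genes, "cell1")), sparse = TRUE)
  count_matrix(m)
}

# A quick small simulated pair at count level, for downstream stats tests.
small_count_pair <- function(seed = 1, stress_fold = 1, ...) {
  spec <- synthetic_spec(n_cell_types = 2, cells_per_type_per_protocol = 40,
                         n_genes = 300, library_size_log_mean = log(500),
                         stress_fold = stress_fold, seed = seed, ...)
  list(spec = spec, cm = simulate_count_pair(spec))
}

# Small molecule-level pair for read-level tests.
small_molecule_pair <- function(seed = 1, ...) {
  spec <- synthetic_spec(n_cell_types = 2, cells_per_type_per_protocol = 20,
                         n_genes = 200, library_size_log_mean = log(300),
                         amplification_mean = 3, seed = seed, ...)
  list(spec = spec, sim = simulate_protocol_pair(spec))
}
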