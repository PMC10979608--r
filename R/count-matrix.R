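#' Sparse cell-by-gene UMI count container
#'
#' Wraps a sparse integer count matrix (genes in rows, cells in columns — the
#' droplet-platform file convention) together with per-cell and per-gene
#' metadata. Cell metadata typically carries protocol, cell-type and QC
#' columns; gene metadata carries `biotype` plus logical `is_mito` / `is_ribo`
#' flags used by QC.
#'
#' @param counts matrix or Matrix of non-negative integers, genes x cells,
#'   with rownames (gene ids) and colnames (barcodes).
#' @param cell_meta data.frame with one row per cell (barcode order); a
#'   `barcode` column is added from colnames if absent.
#' @param gene_meta data.frame with one row per gene; columns `biotype`,
#'   `is_mito`, `is_ribo` are filled with defaults if absent
#'   (`is_mito` from a `^MT-`/`^mt-` gene-id prefix, `is_ribo` from
#'   `^RP[SL]`/`^Rp[sl]`).
#' @return A `count_matrix` object (list with elements `counts`, `cell_meta`,
#'   `gene_meta`).
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stopf("count matrix has negative entries")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0)
      stopf("counts must have rownames (gene ids) and colnames (barcodes)")
    rownames(counts) <- character()
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0)
      stopf("counts must have rownames (gene ids) and colnames (barcodes)")
    colnames(counts) <- character()
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate barcodes")

  if (is.null(cell_meta))
    cell_meta <- data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  if (!"barcode" %in% names(cell_meta)) cell_meta$barcode <- colnames(counts)
  if (nrow(cell_meta) != ncol(counts))
    stopf("cell_meta has %d rows but matrix has %d cells", nrow(cell_meta), ncol(counts))

  if (is.null(gene_meta))
    gene_meta <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(gene_meta)) gene_meta$gene_id <- rownames(counts)
  if (nrow(gene_meta) != nrow(counts))
    stopf("gene_meta has %d rows but matrix has %d genes", nrow(gene_meta), nrow(counts))
  if (!"biotype" %in% names(gene_meta))
    gene_meta$biotype <- rep("unannotated", nrow(gene_meta))
  if (!"is_mito" %in% names(gene_meta))
    gene_meta$is_mito <- grepl("^(MT|mt)-", gene_meta$gene_id)
  if (!"is_ribo" %in% names(gene_meta))
    gene_meta$is_ribo <- grepl("^(RP|Rp)[SsLl]", gene_meta$gene_id)
  rownames(cell_meta) <- cell_meta$barcode
  rownames(gene_meta) <- gene_meta$gene_id

  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %s UMIs\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset keeping metadata aligned; i = gene index/names, j = cell index/names.
subset_cm <- function(x, i = NULL, j = NULL) {
  if (!is.null(i)) {
    x$counts <- x$counts[i, , drop = FALSE]
    x$gene_meta <- x$gene_meta[i, , drop = FALSE]
  }
  if (!is.null(j)) {
    x$counts <- x$counts[, j, drop = FALSE]
    x$cell_meta <- x$cell_meta[j, , drop = FALSE]
  }
  x
}

#' Collapse molecule records to a UMI count matrix
#'
#' Entry (gene, cell) is the number of distinct molecules — (barcode, UMI,
#' gene) triples — observed for that pair. Per-molecule read counts are
#' ignored: a molecule counts once however many reads support it.
#'
#' @param table a [molecule_table()].
#' @param gene_meta optional gene metadata passed through to the result.
#' @return A [count_matrix()]; `0 x 0` for an empty table.
#' @export
collapse_to_matrix <- function(table, gene_meta = NULL) {
  validate_molecule_table(table)
  if (nrow(table) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, 0L))
    rownames(m) <- character(); colnames(m) <- character()
    return(count_matrix(m,
                        cell_meta = data.frame(barcode = character()),
                        gene_meta = data.frame(gene_id = character())))
  }
  genes <- sort(unique(table$gene_id))
  cells <- sort(unique(table$cell_barcode))
  m <- Matrix::sparseMatrix(i = match(table$gene_id, genes),
                            j = match(table$cell_barcode, cells),
                            x = rep(1, nrow(table)),
                            dims = c(length(genes), length(cells)))
  rownames(m) <- genes
  colnames(m) <- cells
  if (!is.null(gene_meta)) gene_meta <- gene_meta[match(genes, gene_meta$gene_id), , drop = FALSE]
  count_matrix(m, gene_meta = gene_meta)
}

#' Read / write a count matrix in Matrix Market format
#'
#' The directory layout follows the droplet-platform convention:
#' `matrix.mtx` (coordinate format, genes x cells), `features.tsv`
#' (`gene_id`, `name`, `biotype`) and `barcodes.tsv` (one barcode per line).
#' Round trips are lossless for counts, gene ids/biotypes and barcodes.
#'
#' @param dir directory containing (or to receive) the three files.
#' @return `read_mtx` returns a [count_matrix()]; `write_mtx` invisibly
#'   returns `dir`.
#' @export
read_mtx <- function(dir) {
  mpath <- file.path(dir, "matrix.mtx")
  fpath <- file.path(dir, "features.tsv")
  bpath <- file.path(dir, "barcodes.tsv")
  for (p in c(mpath, fpath, bpath))
    if (!file.exists(p)) stopf("missing %s", p)
  m <- methods::as(Matrix::readMM(mpath), "CsparseMatrix")
  feats <- data.table::fread(fpath, sep = "\t", header = FALSE,
                             data.table = FALSE, showProgress = FALSE)
  names(feats)[seq_len(min(3, ncol(feats)))] <-
    c("gene_id", "name", "biotype")[seq_len(min(3, ncol(feats)))]
  bcs <- data.table::fread(bpath, sep = "\t", header = FALSE,
                           data.table = FALSE, showProgress = FALSE)[[1]]
  if (nrow(feats) != nrow(m))
    stopf("features.tsv has %d rows but matrix header declares %d genes",
          nrow(feats), nrow(m))
  if (length(bcs) != ncol(m))
    stopf("barcodes.tsv has %d rows but matrix header declares %d cells",
          length(bcs), ncol(m))
  rownames(m) <- feats$gene_id
  colnames(m) <- bcs
  gm <- data.frame(gene_id = feats$gene_id, stringsAsFactors = FALSE)
  if ("biotype" %in% names(feats)) gm$biotype <- feats$biotype
  count_matrix(m, gene_meta = gm)
}

#' @rdname read_mtx
#' @param matrix a [count_matrix()].
#' @export
write_mtx <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  gm <- matrix$gene_meta
  feats <- data.frame(gene_id = gm$gene_id,
                      name = gm$name %||% gm$gene_id,
                      biotype = gm$biotype %||% "unannotated")
  data.table::fwrite(feats, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  data.table::fwrite(data.frame(barcode = colnames(matrix$counts)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors;
#'   `write_gmt` invisibly returns `path`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("GMT line with fewer than 3 fields: %s", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
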