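#' Molecule-level record table
#'
#' One row per distinct molecule: a (cell barcode, UMI, gene) triple together
#' with the number of sequenced reads supporting it. This is the
#' format-agnostic equivalent of the per-molecule information emitted by
#' droplet platforms, and the unit on which read-level downsampling operates.
#'
#' @param cell_barcode,umi,gene_id character vectors of equal length.
#' @param read_count integer vector, all values >= 1.
#' @param library_id single string identifying the library.
#' @return A `molecule_table`: a data.frame with columns `cell_barcode`,
#'   `umi`, `gene_id`, `read_count` and attribute `library_id`.
#' @export
molecule_table <- function(cell_barcode, umi, gene_id, read_count,
                           library_id = "library") {
  df <- data.frame(cell_barcode = as.character(cell_barcode),
                   umi = as.character(umi),
                   gene_id = as.character(gene_id),
                   read_count = as.integer(read_count),
                   stringsAsFactors = FALSE)
  validate_molecule_table(df)
  attr(df, "library_id") <- library_id
  class(df) <- c("molecule_table", "data.frame")
  df
}

validate_molecule_table <- function(df) {
  need <- c("cell_barcode", "umi", "gene_id", "read_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("molecule table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$read_count))
    stopf("non-integer read_count at row %d", which(is.na(df$read_count))[1])
  bad <- which(df$read_count < 1L)
  if (length(bad))
    stopf("read_count < 1 at row %d (every molecule must have >= 1 read)", bad[1])
  key <- paste(df$cell_barcode, df$umi, df$gene_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicate (cell_barcode, umi, gene_id) at row %d", dup[1])
  invisible(df)
}

#' Total sequenced reads in a molecule table
#' @param table a `molecule_table`.
#' @return Integer sum of per-molecule read counts.
#' @export
total_reads <- function(table) sum(as.numeric(table$read_count))

#' @export
print.molecule_table <- function(x, ...) {
  cat(sprintf("molecule_table '%s': %d molecules, %d barcodes, %d genes, %s reads\n",
              attr(x, "library_id") %||% "?", nrow(x),
              length(unique(x$cell_barcode)), length(unique(x$gene_id)),
              format(total_reads(x), big.mark = ",")))
  invisible(x)
}

#' Read / write a molecule table as TSV
#'
#' The on-disk format is a tab-separated file with header columns
#' `cell_barcode`, `umi`, `gene_id`, `read_count`. Reading validates the
#' molecule-table invariants (unique triples, read_count >= 1) and names the
#' first offending row on failure.
#'
#' @param path file path.
#' @param library_id library identifier attached to the returned table;
#'   defaults to the file name without extension.
#' @return `read_molecule_table` returns a [molecule_table()];
#'   `write_molecule_table` invisibly returns `path`.
#' @export
read_molecule_table <- function(path, library_id = NULL) {
  df <- suppressWarnings(data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("cell_barcode", "umi", "gene_id")),
                          data.table = FALSE, showProgress = FALSE))
  need <- c("cell_barcode", "umi", "gene_id", "read_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  rc <- suppressWarnings(as.integer(df$read_count))
  if (nrow(df) && anyNA(rc))
    stopf("%s: non-integer read_count at data row %d", path, which(is.na(rc))[1])
  molecule_table(df$cell_barcode, df$umi, df$gene_id, rc,
                 library_id = library_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_molecule_table
#' @param table a `molecule_table`.
#' @export
write_molecule_table <- function(table, path) {
  validate_molecule_table(table)
  data.table::fwrite(as.data.frame(table)[, c("cell_barcode", "umi", "gene_id", "read_count")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
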