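#' Downsample sequenced reads without replacement
#'
#' Draws exactly `n_reads` of the library's reads, jointly across molecules:
#' the vector of surviving per-molecule read counts is a multivariate
#' hypergeometric draw from the per-molecule read pools (equivalent to
#' sampling `n_reads` individual reads without replacement, updating the
#' remaining pool after every draw). Molecules left with zero reads are
#' removed — at reduced depth a molecule, and possibly its gene, can
#' disappear, which is what drives the saturation curves.
#'
#' @param table a [molecule_table()].
#' @param n_reads number of reads to keep, `0 <= n_reads <= total_reads(table)`.
#' @param seed RNG seed for the draw.
#' @return A [molecule_table()] whose read counts sum to `n_reads` exactly.
#' @export
downsample_reads <- function(table, n_reads, seed = NULL) {
  validate_molecule_table(table)
  R <- total_reads(table)
  if (n_reads > R) stopf("n_reads (%s) exceeds total reads (%s)",
                         format(n_reads), format(R))
  if (n_reads < 0) stopf("n_reads must be >= 0")
  if (n_reads == R) return(table)
  lib <- attr(table, "library_id") %||% "library"
  if (n_reads == 0)
    return(molecule_table(character(), character(), character(), integer(),
                          library_id = lib))
  surv <- with_seed_(seed, {
    picks <- sample.int(R, n_reads)                     # read indices kept
    cum <- cumsum(as.numeric(table$read_count))
    tabulate(findInterval(picks - 1, cum) + 1L, nbins = nrow(table))
  })
  keep <- surv > 0L
  molecule_table(table$cell_barcode[keep], table$umi[keep],
                 table$gene_id[keep], surv[keep], library_id = lib)
}

# Nested downsampling: one read permutation, each depth is a prefix, so
# detected genes/UMIs are non-decreasing along the grid by construction.
# Used for monotone-coupling checks; the public curve uses independent draws.
downsample_reads_nested <- function(table, depths, seed = NULL) {
  validate_molecule_table(table)
  R <- total_reads(table)
  if (any(depths > R)) stopf("depth exceeds total reads")
  lib <- attr(table, "library_id") %||% "library"
  perm <- with_seed_(seed, sample.int(R))
  cum <- cumsum(as.numeric(table$read_count))
  lapply(depths, function(d) {
    if (d == 0)
      return(molecule_table(character(), character(), character(), integer(),
                            library_id = lib))
    surv <- tabulate(findInterval(perm[seq_len(d)] - 1, cum) + 1L,
                     nbins = nrow(table))
    keep <- surv > 0L
    molecule_table(table$cell_barcode[keep], table$umi[keep],
                   table$gene_id[keep], surv[keep], library_id = lib)
  })
}

#' Saturation curve of detected genes and molecules versus depth
#'
#' Downsamples the library to a grid of read depths (independent draw per
#' depth, child seeds from `seed`) and records, at each depth, the number of
#' distinct genes with at least one surviving molecule and the number of
#' surviving molecules (UMIs). The full-depth point is always appended, so
#' the last row equals the library totals exactly.
#'
#' @param table a [molecule_table()].
#' @param depth_step positive step size; the grid is `step, 2*step, ...` up
#'   to full depth. Ignored when `depth_grid` is given.
#' @param depth_grid explicit increasing depths within `(0, total_reads]`.
#' @param n_steps convenience: when neither step nor grid is given, the grid
#'   is `n_steps` equal steps up to full depth (default 10).
#' @param seed RNG seed; each depth uses a derived child seed.
#' @return A `saturation_curve` data.frame with columns `depth`,
#'   `genes_detected`, `umis_detected`.
#' @export
saturation_curve <- function(table, depth_step = NULL, depth_grid = NULL,
                             n_steps = 10, seed = NULL) {
  validate_molecule_table(table)
  if (nrow(table) == 0L) stopf("empty molecule table")
  R <- total_reads(table)
  if (is.null(depth_grid)) {
    step <- depth_step %||% max(1, floor(R / n_steps))
    if (step <= 0) stopf("depth_step must be > 0")
    depth_grid <- seq(step, R, by = step)
  }
  depth_grid <- sort(unique(c(as.numeric(depth_grid), R)))
  if (any(depth_grid <= 0) || any(depth_grid > R))
    stopf("depth grid must lie in (0, total_reads]")
  rows <- lapply(seq_along(depth_grid), function(k) {
    d <- depth_grid[k]
    sub <- if (d == R) table else downsample_reads(table, d, seed = child_seed(seed, 100L + k))
    data.frame(depth = d,
               genes_detected = length(unique(sub$gene_id)),
               umis_detected = nrow(sub))
  })
  out <- do.call(rbind, rows)
  attr(out, "library_id") <- attr(table, "library_id") %||% "library"
  class(out) <- c("saturation_curve", "data.frame")
  out
}

linear_fit_ci <- function(slope, intercept, lo, hi, r2, n, degenerate = FALSE) {
  structure(list(slope = slope, intercept = intercept,
                 slope_ci_low = lo, slope_ci_high = hi,
                 r_squared = r2, n = n, degenerate = degenerate),
            class = "linear_fit_ci")
}

#' @export
print.linear_fit_ci <- function(x, ...) {
  if (x$degenerate)
    cat("linear_fit_ci: degenerate (zero-variance predictor), slope undefined\n")
  else
    cat(sprintf("linear_fit_ci: slope %.4g (95%% CI %.4g to %.4g), intercept %.4g, r^2 %.4f, n = %d\n",
                x$slope, x$slope_ci_low, x$slope_ci_high, x$intercept,
                x$r_squared, x$n))
  invisible(x)
}

# OLS of y on x with the t-based 95% CI of the slope (n - 2 df).
ols_ci <- function(x, y) {
  n <- length(x)
  if (n < 3) stopf("need >= 3 points for a linear fit")
  if (var(x) == 0)
    return(linear_fit_ci(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, n,
                         degenerate = TRUE))
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, "x", level = 0.95))
  r2 <- if (var(y) == 0) 1 else suppressWarnings(summary(fit))$r.squared
  linear_fit_ci(unname(coef(fit)["x"]), unname(coef(fit)["(Intercept)"]),
                ci[1], ci[2], r2, n)
}

#' Linear model of a saturation curve
#'
#' Ordinary least squares of detected genes (or molecules) on sequencing
#' depth, with the 95% confidence interval of the depth coefficient from the
#' t distribution with n - 2 degrees of freedom. Libraries are compared by
#' testing whether these intervals overlap ([ci_overlap_test()]).
#'
#' @param curve a [saturation_curve()] (>= 3 points).
#' @param response `"genes"` or `"umis"`.
#' @return A `linear_fit_ci` (slope in detected count per read).
#' @export
fit_depth_model <- function(curve, response = c("genes", "umis")) {
  response <- match.arg(response)
  y <- if (response == "genes") curve$genes_detected else curve$umis_detected
  ols_ci(curve$depth, y)
}

#' Compare two linear fits by 95% CI overlap
#'
#' The difference between two libraries' complexity slopes is called
#' significant exactly when their 95% confidence intervals are disjoint.
#' Intervals are treated as closed, so touching endpoints count as overlap
#' (not significant) — the conservative convention.
#'
#' @param fit_a,fit_b `linear_fit_ci` objects.
#' @return List with `significant` (logical) and both intervals.
#' @export
ci_overlap_test <- function(fit_a, fit_b) {
  if (isTRUE(fit_a$degenerate) || isTRUE(fit_b$degenerate))
    stopf("cannot compare a degenerate fit")
  overlap <- fit_a$slope_ci_low <= fit_b$slope_ci_high &&
             fit_b$slope_ci_low <= fit_a$slope_ci_high
  list(significant = !overlap,
       interval_a = c(fit_a$slope_ci_low, fit_a$slope_ci_high),
       interval_b = c(fit_b$slope_ci_low, fit_b$slope_ci_high))
}

#' Per-cell library complexity and its depth regression
#'
#' Tabulates reads, molecules (UMIs) and distinct genes per barcode, then
#' regresses genes and UMIs on reads across cells, giving per-library slopes
#' comparable between protocols. Zero-variance reads (all cells identical)
#' yield a fit flagged `degenerate` with undefined slope.
#'
#' @param table a [molecule_table()] with >= 3 barcodes.
#' @return List: `per_cell` (data.frame barcode/reads/umis/genes),
#'   `fit_genes`, `fit_umis` (`linear_fit_ci`).
#' @export
per_cell_complexity <- function(table) {
  validate_molecule_table(table)
  dt <- data.table::as.data.table(as.data.frame(table))
  per <- dt[, list(reads = sum(as.numeric(read_count)), umis = .N,
                   genes = data.table::uniqueN(gene_id)),
            by = "cell_barcode"]
  per <- as.data.frame(per[order(per$cell_barcode)])
  names(per)[1] <- "barcode"
  if (nrow(per) < 3) stopf("need >= 3 barcodes for per-cell complexity fits")
  list(per_cell = per,
       fit_genes = ols_ci(per$reads, per$genes),
       fit_umis = ols_ci(per$reads, per$umis))
}

#' Gene accumulation over increasing numbers of cells
#'
#' For each n in the grid, the mean (over `reps` random draws) number of
#' distinct genes detected in n cells sampled without replacement. Draws are
#' coupled within a repetition (one cell permutation per repetition, each n a
#' prefix), so each repetition's curve is non-decreasing while every n keeps
#' the exact uniform n-subset marginal.
#'
#' @param matrix a [count_matrix()].
#' @param n_grid increasing cell numbers; default 1 to 100 in steps of 2.
#' @param reps repetitions to average over (default 100).
#' @param seed RNG seed.
#' @return An `accumulation_curve` data.frame (`n_cells`, `mean_genes`,
#'   `sd_genes`) with attribute `n_repetitions`.
#' @export
cumulative_gene_curve <- function(matrix, n_grid = seq(1, 100, by = 2),
                                  reps = 100, seed = NULL) {
  m <- matrix$counts
  n_cells <- ncol(m)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (max(n_grid) > n_cells)
    stopf("n_grid extends to %d cells but the matrix has only %d",
          max(n_grid), n_cells)
  # per-cell sets of detected gene indices, from the CSC slot directly
  ptr <- m@p
  gene_sets <- lapply(seq_len(n_cells), function(j) {
    idx <- if (ptr[j + 1] > ptr[j]) m@i[(ptr[j] + 1):ptr[j + 1]] + 1L else integer()
    idx[m@x[(ptr[j] + seq_along(idx))] > 0]
  })
  vals <- with_seed_(seed, {
    vapply(seq_len(reps), function(r) {
      perm <- sample.int(n_cells)
      seen <- logical(nrow(m))
      total <- 0L
      out <- numeric(length(n_grid))
      pos <- 0L
      for (k in seq_along(n_grid)) {
        while (pos < n_grid[k]) {
          pos <- pos + 1L
          g <- gene_sets[[perm[pos]]]
          new <- g[!seen[g]]
          seen[new] <- TRUE
          total <- total + length(new)
        }
        out[k] <- total
      }
      out
    }, numeric(length(n_grid)))
  })
  vals <- base::matrix(vals, nrow = length(n_grid))
  out <- data.frame(n_cells = n_grid,
                    mean_genes = rowMeans(vals),
                    sd_genes = apply(vals, 1, stats::sd))
  attr(out, "n_repetitions") <- reps
  class(out) <- c("accumulation_curve", "data.frame")
  out
}
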