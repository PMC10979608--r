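#' @importFrom stats lm confint coef cor.test loess p.adjust predict quantile
#'   rlnorm rmultinom rnbinom rbinom runif setNames var wilcox.test median
#' @importFrom utils head
NULL

utils::globalVariables(c("umi", "read_count", "gene_id", "cell_barcode"))

.datatable.aware <- TRUE

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic child seed for stage `offset` under master seed; stays < 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
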