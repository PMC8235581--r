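#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom data.table data.table setkey rbindlist
#' @importFrom stats hclust as.dist setNames rbinom runif
#' @importFrom utils write.table read.table head tail
NULL

.datatable.aware <- TRUE

# Run expr with a private, restorable RNG state so library code never
# perturbs the caller's stream. Seeds are plain 32-bit integers.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max,
             kind = "Mersenne-Twister", sample.kind = "Rejection")
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(offset) %% 1000003L
}

round1 <- function(x) round(x, 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of alignment columns (incl. gap columns) per pairwise alignment
aln_ncol <- function(aln) {
  Biostrings::width(Biostrings::alignedPattern(aln))
}
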