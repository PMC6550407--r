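#' @keywords internal
"_PACKAGE"

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# Every randomized routine in the package funnels through this helper, so a
# single master seed makes the whole pipeline reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a substream seed from a master seed and a stage/bin index, keeping the
# result inside the 32-bit integer range. Distinct (seed, index) pairs map to
# distinct streams for all realistic index counts.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 1009 + as.double(index) * 9973) %% 2147483647
}

check_dna <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop(sprintf("non-ACGT character '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]), call. = FALSE)
  }
  invisible(chars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
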