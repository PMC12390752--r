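# Internal helpers: structured errors, bit packing, sequences, seeded RNG.

ddc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ddc_error")))
}

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over `ACGT` (case preserved as upper case).
#' Kept deliberately minimal: trigger-strand derivation and the
#' cross-hybridization screen only ever handle plain upper-case DNA.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# MSB-first bit expansion of a non-negative integer.
int_to_bits <- function(x, nbits) {
  stopifnot(x >= 0, x < 2^nbits)
  rev(as.integer(intToBits(as.integer(x))[seq_len(nbits)]))
}

# Inverse of int_to_bits (MSB first).
bits_to_int <- function(bits) {
  as.integer(sum(bits * 2^(rev(seq_along(bits)) - 1L)))
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
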