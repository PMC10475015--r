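#' Reverse complement of a DNA string
#'
#' @param seq single character string over A/C/G/T/N (lowercase allowed).
#' @return reverse-complemented string, uppercase.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @param gc GC content as a fraction.
#' @return character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# 1-based gap (in bases) between two closed intervals; 0 if they touch/overlap.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
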