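`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are
#' deterministic per seed without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence
#'
#' @param n sequence length in bp.
#' @param gc GC content (probability of G or C per base).
#' @return A single character string of A/C/G/T.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) vapply(x, .revcomp_cpp, character(1), USE.NAMES = FALSE)

# 0-based substring [start, end)
subseq0 <- function(x, start, end) substring(x, start + 1, end)

# splice: replace 0-based [start, end) of x with repl
splice0 <- function(x, start, end, repl) {
  paste0(substring(x, 1, start), repl, substring(x, end + 1, nchar(x)))
}
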