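#' @importFrom stats pnorm rbinom runif setNames
#' @importFrom utils adist head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence with a target GC content
#'
#' @param n sequence length in bp.
#' @param gc target GC fraction in (0, 1).
#' @return A single character string over A/C/G/T.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc > 0, gc < 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## set.seed only when the caller supplied one; NULL leaves the RNG stream alone
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

## strict interval containment helpers (1-based closed coordinates)
contains <- function(outer_start, outer_end, inner_start, inner_end) {
  outer_start <= inner_start & outer_end >= inner_end
}

overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
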