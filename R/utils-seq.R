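#' @import methods
#' @importFrom stats runif rgeom rexp setNames
#' @importFrom utils head tail modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random DNA sequence
#'
#' @param n sequence length in nt.
#' @return a single character string of length `n` over A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# substring by 0-based half-open coordinates, the package-wide convention
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

assert_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x) ||
      grepl("[^ACGT]", x)) {
    stop(what, " must be a non-empty A/C/G/T string", call. = FALSE)
  }
  invisible(x)
}

# Run code with a locally-seeded RNG, restoring global state afterwards.
# All stochastic operations in the package funnel through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# half-away-from-zero rounding (R's round() is round-half-even); the
# convention used for integer-percent reporting
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
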