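# Independent oracles used by the property and acceptance tests.
# These re-derive expected results by brute force and never call the
# package code paths they check.

# Affine-gap DP (Gotoh) oracle. A gap of length L costs go + ge * L.
# type "global": full Needleman-Wunsch; "global-local": query global,
# reference end-gaps free.
oracle_align_score <- function(query, reference, match = 2, mismatch = -4,
                               go = 6, ge = 1, type = "global") {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last column aligned
  X <- matrix(NEG, n + 1, m + 1)  # gap in reference (query base unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in query (reference base unmatched)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
  if (m >= 1) for (j in 2:(m + 1)) {
    Y[1, j] <- if (type == "global-local") 0 else -(go + ge * (j - 1))
    if (type == "global-local") M[1, j] <- 0
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == r[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge,
                     X[i, j - 1] - go - ge)
    }
  }
  if (type == "global-local") {
    max(M[n + 1, ], X[n + 1, ], Y[n + 1, ])
  } else {
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  }
}

# exhaustive window-scanning oracle for protospacer+NGG sites
oracle_scan_sites <- function(locus, proto) {
  n <- nchar(locus)
  plen <- nchar(proto)
  out <- list()
  for (s in 0:(n - plen - 3)) {
    if (substr(locus, s + 1, s + plen) == proto &&
        substr(locus, s + plen + 2, s + plen + 3) == "GG")
      out[[length(out) + 1]] <- list(start = s, strand = "+",
                                     cut = s + plen - 3)
  }
  rcl <- revcomp(locus)
  for (s in 0:(n - plen - 3)) {
    if (substr(rcl, s + 1, s + plen) == proto &&
        substr(rcl, s + plen + 2, s + plen + 3) == "GG") {
      start_fwd <- n - (s + plen)
      out[[length(out) + 1]] <- list(start = start_fwd, strand = "-",
                                     cut = start_fwd + 3)
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "start"))]
}

# brute-force cut-and-ligate oracle: all assemblies of the outer fragments
# with the donor/middle fragment in every orientation and position
oracle_outcome_seqs <- function(locus, cutL, cutR, donor) {
  l <- substr(locus, 1, cutL)
  m <- substr(locus, cutL + 1, cutR)
  r <- substr(locus, cutR + 1, nchar(locus))
  Drc <- revcomp(donor)
  list(original = paste0(l, m, r),
       deletion = paste0(l, r),
       replacement_fwd = paste0(l, donor, r),
       replacement_rev = paste0(l, Drc, r),
       insertion_up_fwd = paste0(l, donor, m, r),
       insertion_up_rev = paste0(l, Drc, m, r),
       insertion_down_fwd = paste0(l, m, donor, r),
       insertion_down_rev = paste0(l, m, Drc, r))
}

# expected number of distinct UMIs when n molecules draw length-k UMIs
# uniformly (birthday collisions)
oracle_expected_distinct_umis <- function(n, k) {
  U <- 4^k
  U * (1 - (1 - 1 / U)^n)
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)
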