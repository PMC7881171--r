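# Shared compact fixtures, built in code at test time.

# the canonical compact directional design used across tests
test_design <- function(seed = 1L) example_design(seed)

# a random toy design with independent guides on random strands, for
# enumeration property tests; returns the design plus the pieces the
# oracle needs
random_toy_design <- function(seed) {
  with_seed(seed, {
    repeat {
      p1 <- random_dna(20); p2 <- random_dna(20)
      s1 <- sample(c("+", "-"), 1); s2 <- sample(c("+", "-"), 1)
      site1 <- paste0(p1, sample(c("A", "C", "G", "T"), 1), "GG")
      site2 <- paste0(p2, sample(c("A", "C", "G", "T"), 1), "GG")
      if (s1 == "-") site1 <- revcomp(site1)
      if (s2 == "-") site2 <- revcomp(site2)
      locus <- paste0(random_dna(60), site1, random_dna(50), site2, random_dna(60))
      g1 <- locate_guide(locus, p1)
      g2 <- locate_guide(locus, p2)
      if (length(g1) != 1 || length(g2) != 1) next
      donor <- random_dna(70)
      des <- try(suppressWarnings(
        replace_design(locus, g1[[1]], g2[[1]], donor)), silent = TRUE)
      if (inherits(des, "try-error")) next
      return(des)
    }
  })
}

quiet_tally <- function(...) suppressWarnings(tally_umis(...))
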