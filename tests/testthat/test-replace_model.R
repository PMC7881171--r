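test_that("locate_guide finds plus- and minus-strand sites with correct cut positions", {
  P <- "ACGTACGTACGTACGTACGT"
  # plus strand: protospacer at offset 3, PAM = AGG
  locus <- paste0("GGG", P, "AGGTT")
  hits <- locate_guide(locus, P)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$strand, "+")
  expect_equal(hits[[1]]$start, 3L)
  expect_equal(hits[[1]]$cut, 20L)
  # minus strand: CCN immediately 5' of the reverse-complemented protospacer
  locus2 <- paste0("TT", "CCA", revcomp(P), "GG")
  hits2 <- locate_guide(locus2, P)
  expect_length(hits2, 1)
  expect_equal(hits2[[1]]$strand, "-")
  expect_equal(hits2[[1]]$start, 5L)
  expect_equal(hits2[[1]]$cut, 8L)
  # two sites, returned in coordinate order
  locus3 <- paste0("AA", P, "AGG", "TTTT", P, "AGG", "AA")
  hits3 <- locate_guide(locus3, P)
  expect_length(hits3, 2)
  expect_true(hits3[[1]]$start < hits3[[2]]$start)
  # empty result is a normal return
  expect_length(locate_guide("ACGTACGTACGTACGTACGTACGTACGT", P), 0)
})

test_that("locate_guide agrees with exhaustive window scanning on random loci", {
  set.seed(42)
  n_hit_checked <- 0
  for (i in 1:200) {
    proto <- random_dna(20)
    locus <- random_dna(500)
    # plant the protospacer most of the time so hits actually occur
    if (runif(1) < 0.8) {
      site <- paste0(proto, "TGG")
      if (runif(1) < 0.5) site <- revcomp(site)
      at <- sample(500 - 23, 1)
      locus <- paste0(substr(locus, 1, at), site, substr(locus, at + 24, 500))
    }
    got <- locate_guide(locus, proto)
    want <- oracle_scan_sites(locus, proto)
    expect_equal(length(got), length(want))
    for (j in seq_along(got)) {
      expect_equal(got[[j]]$start, want[[j]]$start)
      expect_equal(got[[j]]$strand, want[[j]]$strand)
      expect_equal(got[[j]]$cut, want[[j]]$cut)
    }
    n_hit_checked <- n_hit_checked + length(want)
  }
  expect_gt(n_hit_checked, 100)  # the property was exercised, not vacuous
})

test_that("guide_site enforces its invariants", {
  expect_error(guide_site("ACGT", "AGG", "+", 0), "20 nt")
  expect_error(guide_site(strrep("A", 20), "ATT", "+", 0), "NGG")
  expect_error(guide_site(strrep("A", 20), "AGG", "x", 0), "strand")
})

test_that("enumerate_outcomes builds all 8 alleles by perfect ligation", {
  d <- test_design(1)
  out <- enumerate_outcomes(d)
  expect_named(out, c("original", "deletion", "replacement_fwd",
                      "replacement_rev", "insertion_up_fwd", "insertion_up_rev",
                      "insertion_down_fwd", "insertion_down_rev"))
  cutL <- d$guide_left$cut; cutR <- d$guide_right$cut
  l <- substr(d$locus_seq, 1, cutL)
  m <- substr(d$locus_seq, cutL + 1, cutR)
  r <- substr(d$locus_seq, cutR + 1, nchar(d$locus_seq))
  D <- d$donor_seq
  expect_equal(out$replacement_fwd$sequence, paste0(l, D, r))
  expect_equal(out$deletion$sequence, paste0(l, r))
  expect_equal(out$insertion_up_fwd$sequence, paste0(l, D, m, r))
  expect_equal(out$insertion_down_fwd$sequence, paste0(l, m, D, r))
  # junction counts: 0 for original, 1 for deletion, 2 otherwise
  expect_equal(nrow(out$original$junctions), 0)
  expect_equal(nrow(out$deletion$junctions), 1)
  expect_equal(out$deletion$junctions$pos, cutL)
  for (k in names(out)[3:8]) expect_equal(nrow(out[[k]]$junctions), 2)
})

test_that("outcome length arithmetic holds on random designs", {
  for (seed in 1:20) {
    d <- random_toy_design(seed)
    out <- enumerate_outcomes(d)
    excised <- d$guide_right$cut - d$guide_left$cut
    nD <- nchar(d$donor_seq)
    n0 <- nchar(out$original$sequence)
    expect_equal(nchar(out$replacement_fwd$sequence) - n0, nD - excised)
    expect_equal(nchar(out$deletion$sequence), n0 - excised)
    for (k in grep("insertion", names(out), value = TRUE))
      expect_equal(nchar(out[[k]]$sequence), n0 + nD)
  }
})

test_that("junction_recleavable reflects the directional design principle", {
  d <- test_design(1)
  out <- enumerate_outcomes(d)
  guides <- d$guide_left$protospacer
  # deletion junction reforms the full target site of the shared guide
  expect_true(junction_recleavable(out$deletion$sequence,
                                   out$deletion$junctions$pos, guides))
  # correctly integrated donor disrupts the target site at both junctions
  for (p in out$replacement_fwd$junctions$pos)
    expect_false(junction_recleavable(out$replacement_fwd$sequence, p, guides))
  # inverted donor reforms it
  for (p in out$replacement_rev$junctions$pos)
    expect_true(junction_recleavable(out$replacement_rev$sequence, p, guides))
  # PAM mutated away kills recleavability
  proto <- "ACGTACGTACGTACGTACGT"
  seq_ok <- paste0(random_dna(40), proto, "AGG", random_dna(40))
  seq_bad <- sub("AGG", "ATT", seq_ok, fixed = TRUE)
  expect_true(junction_recleavable(seq_ok, 60, proto))
  expect_false(junction_recleavable(seq_bad, 60, proto))
  expect_error(junction_recleavable(seq_ok, 1000, proto), "outside")
})

test_that("validate_design passes a directional design and flags defects", {
  d <- test_design(1)
  rep <- validate_design(d)
  expect_s3_class(rep, "design_report")
  expect_true(rep$buffer_ok)
  expect_length(rep$warnings, 0)
  expect_false(any(rep$recleavable$replacement_fwd))
  expect_true(any(rep$recleavable$deletion))
  expect_true(all(rep$recleavable$replacement_rev))
  expect_gte(rep$n_guides_required, 2)

  # undersized left buffer is named in a warning
  d2 <- test_design(2)
  d2$buffer_left <- 10L; d2$buffer_right <- 40L
  rep2 <- validate_design(d2)
  expect_false(rep2$buffer_ok)
  expect_true(any(grepl("left", rep2$warnings)))

  # a donor that reforms the target site in its designed orientation
  # defeats the capture logic: error unless forced
  cutL <- d$guide_left$cut; cutR <- d$guide_right$cut
  bad_donor <- substr(d$locus_seq, cutL + 1, cutR)  # the excised segment itself
  d_bad <- suppressWarnings(replace_design(d$locus_seq, d$guide_left,
                                           d$guide_right, bad_donor))
  expect_error(validate_design(d_bad), "re-cleavable")
  rep3 <- validate_design(d_bad, force = TRUE)
  expect_true(any(grepl("re-cleavable", rep3$warnings)))
})

test_that("degenerate toy inputs warn rather than error", {
  P <- "ACGTAAGGTCGTACGTACGT"
  locus <- paste0(random_dna(30), P, "AGG", random_dna(5), P, "AGG", random_dna(30))
  sites <- locate_guide(locus, P)
  expect_length(sites, 2)
  expect_warning(
    expect_warning(
      replace_design(locus, sites[[1]], sites[[2]], random_dna(30)),
      "40 nt"),
    "50 nt")
})
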