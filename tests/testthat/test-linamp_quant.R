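test_that("expected references reconstruct each outcome from the anchor", {
  d <- test_design(1)
  cutL <- d$guide_left$cut; cutR <- d$guide_right$cut
  a0 <- cutL - 150L
  anchor <- substr(d$locus_seq, a0 + 1, a0 + 20)
  refs <- build_expected_references(d, anchor)
  expect_length(refs, 8)
  for (r in refs) expect_true(startsWith(r$sequence, anchor))
  # deletion reference: upstream..cutL joined to cutR..downstream
  del_manual <- paste0(substr(d$locus_seq, a0 + 1, cutL),
                       substr(d$locus_seq, cutR + 1, nchar(d$locus_seq)))
  expect_equal(refs$deletion$sequence,
               substr(del_manual, 1, nchar(refs$deletion$sequence)))
  # replacement_rev carries the reverse-complemented donor from the cut
  rev_expect <- paste0(substr(d$locus_seq, a0 + 1, cutL), revcomp(d$donor_seq))
  expect_equal(substr(refs$replacement_rev$sequence, 1, nchar(rev_expect)),
               rev_expect)
  # reference count equals the outcome enumeration count
  expect_equal(length(refs), length(enumerate_outcomes(d)))
  expect_error(build_expected_references(d, "ACGT"), "not found|ambiguous")
  expect_error(build_expected_references(d, substr(d$locus_seq, cutR + 5, cutR + 30)),
               "upstream")
})

test_that("reads are assigned with junction coverage accounting", {
  d <- test_design(1)
  anchor_off <- d$guide_left$cut - 150L
  anchor <- substr(d$locus_seq, anchor_off + 1, anchor_off + 20)
  refs <- build_expected_references(d, anchor)
  ref <- refs$deletion
  j1 <- ref$junctions$pos[1]
  # perfect read spanning the deletion junction by 40 nt each side
  r1 <- substr(ref$sequence, 1, j1 + 40)
  # read reaching only 8 nt past the junction: enough sequence to identify
  # the class (the inverted donor's end shares its first 6 bases with the
  # deletion product in this design), not enough to call the junction
  r_stop <- substr(ref$sequence, 1, j1 + 8)
  # off-primer read
  r_bad <- paste0(random_dna(20), substr(ref$sequence, 21, j1 + 40))
  reads <- data.frame(id = c("a", "b", "c"),
                      sequence = c(r1, r_stop, r_bad),
                      umi = c("AAAA", "CCCC", "GGGG"),
                      stringsAsFactors = FALSE)
  asg <- assign_and_call(reads, refs, min_junction_overlap = 10)
  expect_equal(asg$klass[1], "deletion")
  expect_true(asg$j1_covered[1])
  expect_equal(asg$j1_type[1], "none")
  expect_equal(asg$klass[2], "deletion")
  expect_false(asg$j1_covered[2])
  expect_true(is.na(asg$j1_type[2]))
  expect_equal(asg$klass[3], "discarded")
  expect_equal(asg$reason[3], "off-primer")
  # accounting: discarded + assigned + unclassified = input
  expect_equal(sum(asg$klass == "discarded") +
                 sum(asg$klass == "unclassified") +
                 sum(!asg$klass %in% c("discarded", "unclassified")),
               nrow(reads))
})

test_that("UMI tallying counts molecules with majority conflict resolution", {
  mk <- function(id, umi, klass) data.frame(
    id = id, umi = umi, klass = klass, reason = NA_character_,
    score = 1, margin = 10, j1_covered = TRUE, j1_type = "none",
    j1_size = 0L, j1_inserted = NA_character_, j2_covered = FALSE,
    j2_type = NA_character_, j2_size = NA_integer_,
    j2_inserted = NA_character_, stringsAsFactors = FALSE)
  # 10 reads, 4 distinct UMIs, one class -> 4 molecules
  a <- mk(sprintf("r%d", 1:10), rep(c("AA", "CC", "GG", "TT"), c(4, 3, 2, 1)),
          "replacement_fwd")
  tab <- tally_umis(a)
  expect_equal(tab$n_molecules, 4)
  expect_true(tab$umi_mode)
  # majority: UMI seen 3x replacement_fwd, 1x deletion -> replacement_fwd
  b <- mk(sprintf("r%d", 1:4), "AA", c(rep("replacement_fwd", 3), "deletion"))
  tb <- tally_umis(b)
  expect_equal(tb$table$klass, "replacement_fwd")
  expect_equal(tb$n_molecules, 1)
  # tie -> molecule discarded
  c2 <- mk(sprintf("r%d", 1:4), "AA", rep(c("replacement_fwd", "deletion"), 2))
  expect_error(tally_umis(c2), "no countable")
  d2 <- rbind(mk("x", "GG", "original"), c2)
  td <- tally_umis(d2)
  expect_equal(td$n_conflict_discarded, 1)
  expect_equal(td$n_molecules, 1)
  # no UMIs: falls back to read counting with a warning
  e <- mk(sprintf("r%d", 1:6), NA_character_, "original")
  expect_warning(te <- tally_umis(e), "read-level")
  expect_equal(te$n_molecules, 6)
})

test_that("molecule counts are recovered within the collision-corrected expectation", {
  set.seed(61)
  n_mol <- 2000L
  umis <- vapply(seq_len(n_mol), function(i) random_dna(10), character(1))
  classes <- sample(c("replacement_fwd", "deletion", "original"), n_mol,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
  reps <- pmax(1L, stats::rpois(n_mol, 5))
  idx <- rep(seq_len(n_mol), reps)
  asg <- data.frame(id = sprintf("r%d", seq_along(idx)), umi = umis[idx],
                    klass = classes[idx], reason = NA_character_,
                    score = 1, margin = 10, j1_covered = TRUE,
                    j1_type = "none", j1_size = 0L, j1_inserted = NA_character_,
                    j2_covered = FALSE, j2_type = NA_character_,
                    j2_size = NA_integer_, j2_inserted = NA_character_,
                    stringsAsFactors = FALSE)
  tab <- tally_umis(asg)
  expected <- oracle_expected_distinct_umis(n_mol, 10)
  expect_lt(abs(tab$n_molecules - expected) / expected, 0.02)
})

test_that("tallies are invariant to read order and UMI relabeling", {
  d <- test_design(1)
  mx <- outcome_mixture()
  sim <- simulate_linamp(d, mx, n_reads = 150, seed = 63)
  refs <- build_expected_references(d, sim$anchor_primer)
  asg <- assign_and_call(sim$reads, refs)
  t1 <- tally_umis(asg)
  # permute rows
  asg2 <- asg[sample(nrow(asg)), ]
  t2 <- tally_umis(asg2)
  expect_equal(t1$table, t2$table)
  # bijective UMI renaming
  asg3 <- asg
  map <- setNames(vapply(seq_along(unique(asg$umi)), function(i)
    paste0(random_dna(8), sprintf("%02d", i)), character(1)), unique(asg$umi))
  asg3$umi <- unname(map[asg3$umi])
  t3 <- tally_umis(asg3)
  expect_equal(t1$table, t3$table)
})

test_that("outcome reports expose fractions, orientation ratio and InDel-free rates", {
  d <- test_design(1)
  mx <- outcome_mixture(weights = c(replacement_fwd = 5, replacement_rev = 1) / 6,
                        p_perfect_junction = 1, p_stagger1 = 0, p_stagger2 = 0)
  sim <- simulate_linamp(d, mx, n_reads = 900, seed = 65)
  refs <- build_expected_references(d, sim$anchor_primer)
  rep <- outcome_report(tally_umis(assign_and_call(sim$reads, refs)))
  fwd_frac <- rep$fwd_rev_ratio$replacement$fwd_fraction
  expect_lt(abs(fwd_frac - 5 / 6), 3 * binom_se(5 / 6, 900))
  expect_equal(rep$indelfree$replacement_fwd_j1$fraction, 1)
  # all-original input: fraction 1.0
  sim0 <- simulate_linamp(d, outcome_mixture(weights = c(original = 1)),
                          n_reads = 80, seed = 67)
  rep0 <- outcome_report(tally_umis(assign_and_call(sim0$reads, refs)))
  expect_equal(rep0$fractions$original, 1)
})
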