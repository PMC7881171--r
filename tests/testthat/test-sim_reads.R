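test_that("staggered_insertion returns the PAM-distal protospacer bases", {
  g <- list(protospacer = "GGGGGGGGGGGGGGGACTGG")
  expect_equal(staggered_insertion(g, 1), "C")   # position 17
  expect_equal(staggered_insertion(g, 2), "AC")  # positions 16-17
  expect_error(staggered_insertion(g, 3), "1 or 2")
})

test_that("mutate_junction is the identity under a perfect mixture", {
  d <- test_design(1)
  out <- enumerate_outcomes(d)
  mx <- outcome_mixture(p_perfect_junction = 1, p_stagger1 = 0, p_stagger2 = 0)
  for (k in c("deletion", "replacement_fwd")) {
    res <- mutate_junction(out[[k]], 1, mx, seed = 5)
    expect_equal(res$sequence, out[[k]]$sequence)
    expect_equal(res$truth$type, "none")
  }
  expect_error(mutate_junction(out$deletion, 2, mx), "out of range")
})

test_that("staggered insertions never occur at protospacer-side junctions", {
  d <- test_design(1)
  out <- enumerate_outcomes(d)
  # replacement_fwd junction 1 ligates two protospacer sides in this design
  j <- out$replacement_fwd$junctions[1, ]
  expect_equal(j$left_label, "protospacer-side")
  expect_equal(j$right_label, "protospacer-side")
  mx <- outcome_mixture(p_perfect_junction = 0, p_stagger1 = 0.7, p_stagger2 = 0.3)
  set.seed(11)
  for (i in 1:200) {
    res <- mutate_junction(out$replacement_fwd, 1, mx)
    expect_false(res$truth$type == "insertion")
  }
  # junction 2 ligates two PAM-proximal sides: insertions do occur there
  j2 <- out$replacement_fwd$junctions[2, ]
  expect_equal(j2$left_label, "PAM-proximal")
  expect_equal(j2$right_label, "PAM-proximal")
  types <- replicate(200, mutate_junction(out$replacement_fwd, 2, mx)$truth$type)
  expect_gt(mean(types == "insertion"), 0.5)
})

test_that("small-deletion sizes follow the geometric distribution", {
  d <- test_design(1)
  out <- enumerate_outcomes(d)
  mx <- outcome_mixture(p_perfect_junction = 0, p_stagger1 = 0, p_stagger2 = 0,
                        del_geom_p = 0.3, p_large_resection = 0)
  set.seed(13)
  sizes <- replicate(1e4, mutate_junction(out$deletion, 1, mx)$truth$size)
  # support starts at 1, so the mean is 1/p; compare within 3 SE
  se <- sqrt(1 - 0.3) / 0.3 / sqrt(1e4)
  expect_lt(abs(mean(sizes) - 1 / 0.3), 3 * se)
  expect_gte(min(sizes), 1)
})

test_that("simulate_longread emits exact amplicons when mutation is off", {
  d <- test_design(1)
  mx <- outcome_mixture(p_perfect_junction = 1, p_stagger1 = 0, p_stagger2 = 0)
  sim <- simulate_longread(d, mx, 50, seed = 3)
  amps <- vapply(expected_amplicons(d), `[[`, character(1), "sequence")
  expect_true(all(sim$reads$sequence %in% amps))
  expect_equal(sim$reads$sequence, unname(amps[sim$truth$klass]))
  # truth table is complete: every read id exactly once
  expect_equal(sort(sim$truth$id), sort(unique(sim$reads$id)))
  # all-original mixture yields only the unedited amplicon
  sim0 <- simulate_longread(d, outcome_mixture(weights = c(original = 1)),
                            30, seed = 4)
  expect_true(all(sim0$reads$sequence == amps["original"]))
})

test_that("PCR length bias over-represents shorter amplicons", {
  d <- test_design(1)
  mx <- outcome_mixture(weights = c(original = 0.5, deletion = 0.5),
                        p_perfect_junction = 1, p_stagger1 = 0, p_stagger2 = 0)
  sim <- simulate_longread(d, mx, 400, length_bias_alpha = 0.01, seed = 5)
  # the deletion amplicon is ~183 nt shorter; at alpha = 0.01 its effective
  # weight is exp(1.83)-fold higher
  expect_gt(mean(sim$truth$klass == "deletion"), 0.75)
  expect_error(simulate_longread(d, mx, 10, primer_left_offset = 500),
               "flank")
})

test_that("class fractions converge to mixture weights without bias", {
  d <- test_design(1)
  mx <- outcome_mixture()
  sim <- simulate_longread(d, mx, 3000, seed = 6)
  frac <- table(factor(sim$truth$klass, names(mx$weights))) / 3000
  for (k in names(mx$weights)) {
    se <- binom_se(mx$weights[[k]], 3000)
    expect_lt(abs(frac[[k]] - mx$weights[[k]]), 3 * se + 1e-9)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  d <- test_design(1)
  mx <- outcome_mixture()
  a <- simulate_longread(d, mx, 40, seed = 17)
  b <- simulate_longread(d, mx, 40, seed = 17)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("UMI collisions match the birthday expectation", {
  d <- test_design(1)
  mx <- outcome_mixture()
  sim <- simulate_linamp(d, mx, n_reads = 1e4, umi_len = 10, seed = 19)
  n_distinct <- length(unique(sim$reads$umi))
  expected <- oracle_expected_distinct_umis(1e4, 10)
  n_coll <- 1e4 - expected
  expect_lt(abs(n_distinct - expected), 3 * sqrt(n_coll) + 1)
})

test_that("donor-anchored simulation recovers the concatemer rate as truth", {
  d <- test_design(1)
  g <- simulate_genome(n_chrom = 3, chrom_len = 3e4, n_offtarget_sites = 6,
                       seed = 21, design = d, n_integration_loci = 6)
  sim <- simulate_linamp(d, n_reads = 3000, anchor = "donor_primer",
                         genome = g, p_concat = 0.34, p_offtarget = 0.06,
                         read_len = 200, shear_min = 120, seed = 22)
  frac <- mean(sim$truth$category == "concatemer")
  expect_lt(abs(frac - 0.34), 3 * binom_se(0.34, 3000))
  # with both event rates zero, every donor-anchored read continues into
  # the target locus
  sim0 <- simulate_linamp(d, n_reads = 100, anchor = "donor_primer",
                          genome = g, read_len = 200, shear_min = 120, seed = 23)
  expect_true(all(sim0$truth$category == "on_target"))
  locus_after_cut <- substr(d$locus_seq, d$guide_right$cut + 1, nchar(d$locus_seq))
  post_donor <- substr(sim0$reads$sequence, nchar(sim0$donor_tail) + 1, 1e4)
  for (fl in post_donor)
    expect_equal(substr(locus_after_cut, 1, nchar(fl)), fl)
})

test_that("synthetic genomes are reproducible and internally consistent", {
  d <- test_design(1)
  g1 <- simulate_genome(n_chrom = 3, chrom_len = 3e4, n_offtarget_sites = 4,
                        seed = 31, design = d, n_integration_loci = 3)
  g2 <- simulate_genome(n_chrom = 3, chrom_len = 3e4, n_offtarget_sites = 4,
                        seed = 31, design = d, n_integration_loci = 3)
  f1 <- tempfile(fileext = ".fasta"); b1 <- tempfile(fileext = ".bed")
  f2 <- tempfile(fileext = ".fasta"); b2 <- tempfile(fileext = ".bed")
  write_genome(g1, f1, b1); write_genome(g2, f2, b2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(b1), readLines(b2))
  # requested number of predicted sites lands in the BED
  expect_length(g1$predicted, 4)
  # every planted event falls within its chromosome
  for (i in seq_len(nrow(g1$planted))) {
    p <- g1$planted[i, ]
    expect_true(p$pos >= 0 && p$pos < nchar(g1$seqs[[p$chrom]]))
  }
  # planted loci respect the predicted-site exclusion distance
  pred <- g1$predicted
  for (i in which(g1$planted$type == "off_target_integration")) {
    p <- g1$planted[i, ]
    sel <- as.character(GenomicRanges::seqnames(pred)) == p$chrom
    if (any(sel)) {
      dmin <- min(abs(BiocGenerics::start(pred)[sel] - 1 - p$pos))
      expect_gte(dmin, 5100 - 23)
    }
  }
})

test_that("a mixture config round-trips through YAML", {
  mx <- outcome_mixture(p_perfect_junction = 0.9, p_stagger1 = 0.05,
                        p_stagger2 = 0.01)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(weights = as.list(mx$weights),
                        p_perfect_junction = 0.9, p_stagger1 = 0.05,
                        p_stagger2 = 0.01), path)
  mx2 <- read_mixture_yaml(path)
  expect_equal(mx2$weights, mx$weights)
  expect_equal(mx2$p_perfect_junction, 0.9)
})

test_that("inconsistent mixtures are rejected", {
  expect_error(outcome_mixture(p_perfect_junction = 0.9, p_stagger1 = 0.2),
               "<= 1")
  expect_error(outcome_mixture(weights = c(bogus = 1)), "outcome classes")
})
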