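#' Run the end-to-end demonstration workflow
#'
#' Generates a compact directional design, simulates a long-read amplicon
#' library and both single-primer libraries from it, runs design
#' validation, structural-variant classification, UMI quantification and
#' integration mapping, and writes all artifacts plus a combined summary
#' JSON. Fully deterministic given the seed.
#'
#' @param seed integer seed driving every stochastic step.
#' @param outdir output directory (created if missing).
#' @param n_longread,n_linamp,n_donor reads per simulated library.
#' @return (invisibly) the combined summary list.
#' @export
run_demo <- function(seed = 7L, outdir = "replaceq_demo",
                     n_longread = 400L, n_linamp = 400L, n_donor = 150L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  design <- example_design(seed)
  mixture <- outcome_mixture()
  report <- validate_design(design)
  write_json(as.list(report), file.path(outdir, "design_report.json"))

  lr <- simulate_longread(design, mixture, n_longread, seed = seed + 1L)
  write_fastq(lr$reads, file.path(outdir, "longread.fastq"))
  write_tsv(lr$truth, file.path(outdir, "longread_truth.tsv"))
  exp_amp <- expected_amplicons(design)
  calls <- classify_reads(lr$reads, exp_amp)
  write_tsv(calls$calls, file.path(outdir, "longread_calls.tsv"))
  osum <- orientation_summary(calls)
  idf <- junction_indelfree_fraction(calls, "replacement_fwd", 1L)
  prof <- deletion_profile(calls, "replacement_fwd")
  write_tsv(prof, file.path(outdir, "deletion_profile.tsv"))

  la <- simulate_linamp(design, mixture, n_reads = n_linamp, seed = seed + 2L)
  write_fastq(la$reads, file.path(outdir, "linamp.fastq"))
  refs <- build_expected_references(design, la$anchor_primer)
  asg <- assign_and_call(read_fastq(file.path(outdir, "linamp.fastq")), refs)
  tab <- tally_umis(asg)
  rep1 <- outcome_report(tab)
  write_json(rep1, file.path(outdir, "pipeline1_report.json"))

  genome <- simulate_genome(n_chrom = 3L, chrom_len = 5e4L,
                            n_offtarget_sites = 10L, seed = seed + 3L,
                            design = design, n_integration_loci = 5L)
  write_genome(genome, file.path(outdir, "genome.fasta"),
               file.path(outdir, "predicted_offtargets.bed"))
  dp <- simulate_linamp(design, mixture, n_reads = n_donor,
                        anchor = "donor_primer", genome = genome,
                        p_offtarget = 0.11, p_concat = 0.34, seed = seed + 4L)
  icalls <- map_integrations(dp$reads, dp$anchor_primer, dp$donor_tail,
                             design, genome)
  write_tsv(icalls, file.path(outdir, "pipeline2_calls.tsv"))
  sites <- cluster_sites(icalls)
  prox <- offtarget_proximity(sites, genome$predicted)
  write_tsv(prox$sites, file.path(outdir, "integration_sites.tsv"))

  cat_tab <- table(icalls$category)
  summary <- list(
    provenance = list(package = "replaceq",
                      version = as.character(utils::packageVersion("replaceq")),
                      seed = seed,
                      n_longread = n_longread, n_linamp = n_linamp,
                      n_donor = n_donor),
    design = list(locus_len = nchar(design$locus_seq),
                  donor_len = nchar(design$donor_seq),
                  cutL = design$guide_left$cut, cutR = design$guide_right$cut,
                  buffer_ok = report$buffer_ok,
                  n_warnings = length(report$warnings)),
    longread = list(
      n_reads = nrow(lr$reads),
      class_fractions = setNames(as.list(osum$fraction_classified), osum$klass),
      replacement_fwd_fraction_within_pair =
        osum$fraction_within_pair[osum$klass == "replacement_fwd"],
      indelfree_replacement_fwd_j1 = idf$fraction),
    pipeline1 = rep1,
    pipeline2 = list(
      n_reads = nrow(icalls),
      category_counts = setNames(as.list(as.integer(cat_tab)), names(cat_tab)),
      n_sites = nrow(prox$sites),
      n_within_proximity = prox$summary$n_within_proximity),
    stats_example = list(
      triploid_to_diploid = setNames(
        as.list(as_percent(ploidy_convert(c(0.58, 0.39, 0.19), 3, 2))),
        c("f58", "f39", "f19")))
  )
  write_json(summary, file.path(outdir, "summary.json"))
  invisible(summary)
}
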