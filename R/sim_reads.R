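#' Outcome mixture and junction-mutation model
#'
#' Describes a population of edited alleles: weights over the eight
#' structural outcome classes, and the per-junction mutation spectrum NHEJ
#' ligation leaves behind. A ligated junction is InDel-free with
#' `p_perfect_junction`; junctions joining two PAM-proximal break ends can
#' instead carry a templated +1/+2 insertion from staggered-cut fill-in
#' (`p_stagger1`, `p_stagger2`); all remaining mass is resection, drawn as
#' a geometric small deletion (support starting at 1) with an occasional
#' exponential large-resection tail applied to one uniformly chosen side of
#' the junction (large resections are asymmetric).
#'
#' Defaults mirror a typical Replace experiment: class weights from
#' single-primer quantification of an endogenous exon replacement (39%
#' designed-orientation replacement, 5:1 orientation ratio, 26% deletion,
#' 16% unedited, remainder insertions), 79% InDel-free junctions, and rare
#' large resections on a ~300 nt scale.
#'
#' @param weights named numeric over the 8 outcome classes; normalized to
#'   sum to 1.
#' @param p_perfect_junction probability a ligated junction is InDel-free.
#' @param p_stagger1,p_stagger2 probabilities of a 1-nt / 2-nt templated
#'   staggered-cut insertion (realized only at PAM/PAM junctions; at other
#'   junctions the drawn mass falls through to resection).
#' @param del_geom_p geometric parameter of the small-deletion size
#'   (mean `1/del_geom_p`).
#' @param p_large_resection probability a deletion additionally carries an
#'   exponential large-resection component.
#' @param large_resection_scale mean of the exponential large-resection
#'   size in nt.
#' @return an `outcome_mixture` object.
#' @export
outcome_mixture <- function(weights = c(original = 0.16, deletion = 0.26,
                                        replacement_fwd = 0.39,
                                        replacement_rev = 0.078,
                                        insertion_up_fwd = 0.028,
                                        insertion_up_rev = 0.028,
                                        insertion_down_fwd = 0.028,
                                        insertion_down_rev = 0.028),
                            p_perfect_junction = 0.79,
                            p_stagger1 = 0.10, p_stagger2 = 0.03,
                            del_geom_p = 0.3,
                            p_large_resection = 0.02,
                            large_resection_scale = 300) {
  w <- setNames(rep(0, length(OUTCOME_CLASSES)), OUTCOME_CLASSES)
  if (is.null(names(weights)) || !all(names(weights) %in% OUTCOME_CLASSES))
    stop("weights must be named with outcome classes: ",
         paste(OUTCOME_CLASSES, collapse = ", "), call. = FALSE)
  w[names(weights)] <- weights
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative and not all zero", call. = FALSE)
  w <- w / sum(w)
  probs <- c(p_perfect_junction, p_stagger1, p_stagger2, del_geom_p,
             p_large_resection)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]", call. = FALSE)
  if (p_perfect_junction + p_stagger1 + p_stagger2 > 1)
    stop("p_perfect + p_stagger1 + p_stagger2 must be <= 1", call. = FALSE)
  if (del_geom_p <= 0) stop("del_geom_p must be > 0", call. = FALSE)
  structure(list(weights = w, p_perfect_junction = p_perfect_junction,
                 p_stagger1 = p_stagger1, p_stagger2 = p_stagger2,
                 del_geom_p = del_geom_p, p_large_resection = p_large_resection,
                 large_resection_scale = large_resection_scale),
            class = "outcome_mixture")
}

#' Templated nucleotides duplicated by a staggered Cas9 cut
#'
#' SpyCas9 sometimes cuts the non-target strand 1-2 nt PAM-distal of the
#' canonical blunt position, leaving a 5' overhang on the PAM-proximal
#' fragment. Fill-in of that overhang duplicates protospacer position 17
#' (1-nt stagger) or positions 16-17 (2-nt), immediately PAM-distal to the
#' canonical cut. When two filled PAM-proximal ends are ligated, these
#' bases appear as a small templated insertion at the junction.
#'
#' @param guide a [guide_site()] (or any list with a `protospacer` field).
#' @param overhang_len 1 or 2.
#' @return the duplicated nucleotide(s) in protospacer sense.
#' @export
staggered_insertion <- function(guide, overhang_len) {
  if (!overhang_len %in% c(1L, 2L)) stop("overhang_len must be 1 or 2", call. = FALSE)
  p <- guide$protospacer
  substr(p, 18L - overhang_len, 17L)
}

# staggered-insertion string as it appears on the allele top strand, given
# the protospacer orientation of the contributing break end
stagger_for_side <- function(protospacer, strand, overhang_len) {
  s <- staggered_insertion(list(protospacer = protospacer), overhang_len)
  if (strand == "-") revcomp(s) else s
}

# Draw one junction's fate. Returns the edited sequence plus a truth record.
# `left_bound`/`right_bound` clamp resection so it cannot run through a
# neighbouring junction or off the molecule.
mutate_one_junction <- function(seq, jrow, mixture, left_bound = 0L,
                                right_bound = nchar(seq)) {
  pos <- jrow$pos
  truth <- list(type = "none", size = 0L, side = NA_character_,
                inserted = NA_character_)
  u <- runif(1)
  p0 <- mixture$p_perfect_junction
  p1 <- p0 + mixture$p_stagger1
  p2 <- p1 + mixture$p_stagger2
  pam_pam <- jrow$left_label == SIDE_PAM && jrow$right_label == SIDE_PAM
  if (u < p0) return(list(sequence = seq, truth = truth))
  if (u < p2 && pam_pam) {
    len <- if (u < p1) 1L else 2L
    if (!is.na(jrow$left_protospacer)) {
      ins <- stagger_for_side(jrow$left_protospacer, jrow$left_strand, len)
    } else if (!is.na(jrow$right_protospacer)) {
      ins <- stagger_for_side(jrow$right_protospacer, jrow$right_strand, len)
    } else {
      ins <- NULL  # no guide recorded for either end: cannot template fill-in
    }
    if (!is.null(ins)) {
      truth$type <- "insertion"; truth$size <- len; truth$inserted <- ins
      newseq <- paste0(substr0(seq, 0L, pos), ins, substr0(seq, pos, nchar(seq)))
      return(list(sequence = newseq, truth = truth))
    }
  }
  # resection: geometric small deletion, exponential tail, one side only
  size <- rgeom(1, mixture$del_geom_p) + 1L
  if (runif(1) < mixture$p_large_resection)
    size <- size + as.integer(round(rexp(1, 1 / mixture$large_resection_scale)))
  side <- sample(c("left", "right"), 1L)
  if (side == "left") {
    size <- min(size, pos - left_bound)
    newseq <- paste0(substr0(seq, 0L, pos - size), substr0(seq, pos, nchar(seq)))
  } else {
    size <- min(size, right_bound - pos)
    newseq <- paste0(substr0(seq, 0L, pos), substr0(seq, pos + size, nchar(seq)))
  }
  truth$type <- if (size > 0L) "deletion" else "none"
  truth$size <- as.integer(size)
  truth$side <- side
  list(sequence = newseq, truth = truth)
}

# Apply the junction mutation model to every junction of an allele.
# Junctions are processed right-to-left so coordinates of still-unprocessed
# junctions remain valid. Returns the mutated sequence and a truth table
# (one row per junction, ascending junction index, positions in
# unmutated-allele coordinates) plus the interval of original coordinates
# removed by resection (for amplifiability checks).
mutate_allele <- function(allele, mixture) {
  js <- allele$junctions
  seq <- allele$sequence
  n <- nrow(js)
  if (n == 0L) {
    return(list(sequence = seq,
                truth = data.frame(junction = integer(0), pos = integer(0),
                                   type = character(0), size = integer(0),
                                   side = character(0), inserted = character(0),
                                   stringsAsFactors = FALSE),
                removed_lo = NA_integer_, removed_hi = NA_integer_))
  }
  bounds_lo <- c(0L, js$pos[-n])
  bounds_hi <- c(js$pos[-1L], nchar(seq))
  rows <- vector("list", n)
  removed_lo <- NA_integer_; removed_hi <- NA_integer_
  for (i in rev(seq_len(n))) {
    res <- mutate_one_junction(seq, js[i, ], mixture,
                               left_bound = bounds_lo[i], right_bound = bounds_hi[i])
    seq <- res$sequence
    tr <- res$truth
    if (tr$type == "deletion") {
      lo <- if (tr$side == "left") js$pos[i] - tr$size else js$pos[i]
      hi <- lo + tr$size
      removed_lo <- min(removed_lo, lo, na.rm = TRUE)
      removed_hi <- max(removed_hi, hi, na.rm = TRUE)
    }
    rows[[i]] <- data.frame(junction = i, pos = js$pos[i], type = tr$type,
                            size = tr$size, side = tr$side,
                            inserted = tr$inserted, stringsAsFactors = FALSE)
  }
  list(sequence = seq, truth = do.call(rbind, rows),
       removed_lo = removed_lo, removed_hi = removed_hi)
}

#' Mutate one junction of an outcome allele
#'
#' Applies the NHEJ junction-mutation model (perfect ligation, templated
#' staggered-cut insertion at PAM/PAM junctions, or one-sided resection) to
#' a single junction and returns the edited full-length sequence with a
#' truth record.
#'
#' @param allele an `outcome_allele` from [enumerate_outcomes()].
#' @param junction_index 1-based junction index.
#' @param mixture an [outcome_mixture()].
#' @param seed optional integer seed.
#' @return list with `sequence` and `truth` (`type`, `size`, `side`,
#'   `inserted`).
#' @export
mutate_junction <- function(allele, junction_index, mixture, seed = NULL) {
  js <- allele$junctions
  if (junction_index < 1 || junction_index > nrow(js))
    stop("junction_index out of range; allele has ", nrow(js), " junction(s)",
         call. = FALSE)
  with_seed(seed, {
    n <- nrow(js)
    lo <- if (junction_index == 1L) 0L else js$pos[junction_index - 1L]
    hi <- if (junction_index == n) nchar(allele$sequence) else js$pos[junction_index + 1L]
    mutate_one_junction(allele$sequence, js[junction_index, ], mixture,
                        left_bound = lo, right_bound = hi)
  })
}

#' Simulate full-length long-read amplicons from a Replace experiment
#'
#' Emits truth-tagged reads spanning the full amplicon between two primers
#' flanking both cuts, from a mixture of outcome alleles whose junctions
#' carry the NHEJ mutation spectrum. Two-primer PCR over-represents short
#' amplicons; `length_bias_alpha > 0` reweights each allele by
#' `exp(-alpha * amplicon_length)` to emulate that bias (0 disables it).
#' Molecules whose resection erodes a primer site cannot be amplified and
#' are redrawn (tallied in `n_resampled`).
#'
#' @param design a [replace_design()].
#' @param mixture an [outcome_mixture()].
#' @param n_reads number of reads.
#' @param primer_left_offset 0-based start of the forward primer footprint
#'   in the locus (must lie upstream of the left cut).
#' @param primer_right_offset distance of the reverse primer footprint from
#'   the locus 3' end (must lie downstream of the right cut).
#' @param length_bias_alpha PCR length-bias coefficient per nt.
#' @param seed integer seed.
#' @param primer_len nominal primer footprint length used for the
#'   amplifiability check.
#' @return list with `reads` (data.frame `id`, `sequence`, `qualities`,
#'   `umi` = NA), `truth` (one row per read: class plus per-junction InDel
#'   truth), `weights_used`, and `n_resampled`.
#' @export
simulate_longread <- function(design, mixture, n_reads,
                              primer_left_offset = 50L,
                              primer_right_offset = 50L,
                              length_bias_alpha = 0, seed = 1L,
                              primer_len = 20L) {
  outcomes <- enumerate_outcomes(design)
  cutL <- design$guide_left$cut
  cutR <- design$guide_right$cut
  locus_len <- nchar(design$locus_seq)
  if (primer_left_offset + primer_len > cutL ||
      primer_right_offset + primer_len > locus_len - cutR)
    stop("primer offsets must flank both cuts in the original allele", call. = FALSE)

  amp_len <- vapply(outcomes, function(a)
    nchar(a$sequence) - primer_left_offset - primer_right_offset, numeric(1))
  w <- mixture$weights * exp(-length_bias_alpha * amp_len)
  if (sum(w) <= 0) stop("all sampling weights vanished", call. = FALSE)
  w <- w / sum(w)

  with_seed(seed, {
    reads <- vector("list", n_reads)
    truth <- vector("list", n_reads)
    n_resampled <- 0L
    for (i in seq_len(n_reads)) {
      repeat {
        k <- sample(names(w), 1L, prob = w)
        allele <- outcomes[[k]]
        mut <- mutate_allele(allele, mixture)
        a_len <- nchar(allele$sequence)
        # molecule must retain both primer footprints
        ok <- is.na(mut$removed_lo) ||
          (mut$removed_lo >= primer_left_offset + primer_len &&
           mut$removed_hi <= a_len - primer_right_offset - primer_len)
        if (ok) break
        n_resampled <- n_resampled + 1L
      }
      amp <- substr0(mut$sequence, primer_left_offset,
                     nchar(mut$sequence) - primer_right_offset)
      id <- sprintf("lr_%06d", i)
      reads[[i]] <- data.frame(id = id, sequence = amp,
                               qualities = strrep("I", nchar(amp)),
                               umi = NA_character_, stringsAsFactors = FALSE)
      tt <- mut$truth
      row <- data.frame(id = id, klass = k, read_len = nchar(amp),
                        stringsAsFactors = FALSE)
      for (j in 1:2) {
        jr <- if (nrow(tt) >= j) tt[j, ] else NULL
        row[[paste0("j", j, "_type")]] <- if (is.null(jr)) NA_character_ else jr$type
        row[[paste0("j", j, "_size")]] <- if (is.null(jr)) NA_integer_ else jr$size
        row[[paste0("j", j, "_side")]] <- if (is.null(jr)) NA_character_ else jr$side
        row[[paste0("j", j, "_inserted")]] <- if (is.null(jr)) NA_character_ else jr$inserted
      }
      truth[[i]] <- row
    }
    list(reads = do.call(rbind, reads), truth = do.call(rbind, truth),
         weights_used = w, n_resampled = n_resampled)
  })
}

#' Simulate a single-primer linear-amplification (UDiTaS/LAM-style) library
#'
#' Reads start at a gene-specific anchor primer and extend a random,
#' tagmentation-determined distance across the ligated junction(s). With a
#' genomic anchor (`anchor = "genomic_primer"`) the library samples the
#' outcome mixture at the target locus (pipeline-1 input). With a donor
#' anchor (`anchor = "donor_primer"`) reads run from inside the donor out
#' through its ligated end into whatever follows: the target locus
#' (on-target), a planted genomic integration site (with `p_offtarget`),
#' or another donor copy head-to-tail / head-to-head (with `p_concat`;
#' pipeline-2 input). Every read carries a `umi_len`-mer UMI; molecules may
#' be sampled more than once via `mean_reads_per_molecule`.
#'
#' @param design a [replace_design()].
#' @param mixture an [outcome_mixture()] (genomic-anchor mode).
#' @param n_reads number of reads for donor-anchored mode, or when
#'   `n_molecules` is NULL.
#' @param anchor `"genomic_primer"` or `"donor_primer"`.
#' @param genome a [simulate_genome()] object (required for donor anchor).
#' @param anchor_offset 0-based primer start: in the locus (genomic anchor;
#'   default 150 nt upstream of the left cut) or distance of the primer
#'   start from the donor 3' end (donor anchor; default 60).
#' @param umi_len UMI length (default 10).
#' @param read_len maximum read length.
#' @param shear_min minimum read length from the tagmentation/shear draw
#'   (default 80% of `read_len`).
#' @param p_offtarget,p_concat donor-anchor event probabilities.
#' @param n_molecules if not NULL, simulate this many distinct molecules
#'   and draw reads from them (UMI and outcome shared within a molecule).
#' @param mean_reads_per_molecule mean reads sampled per molecule.
#' @param primer_len anchor primer footprint length.
#' @param seed integer seed.
#' @return list with `reads` (with `umi`), `truth`, and `anchor_primer`.
#' @export
simulate_linamp <- function(design, mixture = outcome_mixture(), n_reads = 1000L,
                            anchor = c("genomic_primer", "donor_primer"),
                            genome = NULL, anchor_offset = NULL,
                            umi_len = 10L, read_len = 420L, shear_min = NULL,
                            p_offtarget = 0, p_concat = 0,
                            n_molecules = NULL, mean_reads_per_molecule = 1,
                            primer_len = 20L, seed = 1L) {
  anchor <- match.arg(anchor)
  if (is.null(shear_min)) shear_min <- as.integer(round(0.8 * read_len))
  with_seed(seed, {
    if (anchor == "genomic_primer") {
      sim_linamp_genomic(design, mixture, n_reads, anchor_offset, umi_len,
                         read_len, shear_min, n_molecules,
                         mean_reads_per_molecule, primer_len)
    } else {
      if (is.null(genome)) stop("donor-anchored simulation requires a synthetic genome",
                                call. = FALSE)
      sim_linamp_donor(design, genome, n_reads, anchor_offset, umi_len,
                       read_len, shear_min, p_offtarget, p_concat, primer_len)
    }
  })
}

sim_linamp_genomic <- function(design, mixture, n_reads, anchor_offset,
                               umi_len, read_len, shear_min, n_molecules,
                               mean_reads_per_molecule, primer_len) {
  cutL <- design$guide_left$cut
  if (is.null(anchor_offset)) anchor_offset <- max(0L, cutL - 150L)
  if (anchor_offset + primer_len > cutL)
    stop("genomic anchor primer must bind upstream of the left cut", call. = FALSE)
  anchor_primer <- substr0(design$locus_seq, anchor_offset, anchor_offset + primer_len)
  outcomes <- enumerate_outcomes(design)
  w <- mixture$weights

  n_mol <- if (is.null(n_molecules)) n_reads else n_molecules
  mol_class <- sample(names(w), n_mol, replace = TRUE, prob = w)
  mol_umi <- vapply(seq_len(n_mol), function(i) random_dna(umi_len), character(1))
  mol_seq <- character(n_mol)
  mol_truth <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    mut <- mutate_allele(outcomes[[mol_class[i]]], mixture)
    mol_seq[i] <- mut$sequence
    mol_truth[[i]] <- mut$truth
  }
  reads_per_mol <- if (is.null(n_molecules)) rep(1L, n_mol) else
    pmax(1L, stats::rpois(n_mol, mean_reads_per_molecule))
  idx <- rep(seq_len(n_mol), reads_per_mol)
  n_tot <- length(idx)
  lens <- as.integer(round(runif(n_tot, shear_min, read_len)))
  seqs <- substr(mol_seq[idx], anchor_offset + 1L,
                 pmin(nchar(mol_seq[idx]), anchor_offset + lens))
  ids <- sprintf("la_%06d", seq_len(n_tot))
  reads <- data.frame(id = ids, sequence = seqs,
                      qualities = strrep("I", nchar(seqs)),
                      umi = mol_umi[idx], stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, molecule = idx, klass = mol_class[idx],
                      umi = mol_umi[idx], stringsAsFactors = FALSE)
  j1 <- vapply(mol_truth, function(t) if (nrow(t) >= 1) t$type[1] else NA_character_, character(1))
  j2 <- vapply(mol_truth, function(t) if (nrow(t) >= 2) t$type[2] else NA_character_, character(1))
  truth$j1_type <- j1[idx]; truth$j2_type <- j2[idx]
  list(reads = reads, truth = truth, anchor_primer = anchor_primer,
       n_molecules = n_mol)
}

sim_linamp_donor <- function(design, genome, n_reads, anchor_offset, umi_len,
                             read_len, shear_min, p_offtarget, p_concat,
                             primer_len) {
  D <- design$donor_seq
  nD <- nchar(D)
  if (is.null(anchor_offset)) anchor_offset <- 60L
  if (anchor_offset + primer_len > nD)
    stop("donor anchor primer does not fit in the donor", call. = FALSE)
  p_start <- nD - anchor_offset
  anchor_primer <- substr0(D, p_start, p_start + primer_len)
  donor_tail <- substr0(D, p_start, nD)  # primer through the ligated donor end
  ot <- genome$on_target
  if (is.null(ot)) stop("genome has no embedded on-target locus", call. = FALSE)
  planted <- genome$planted[genome$planted$type == "off_target_integration", ]
  if (p_offtarget > 0 && nrow(planted) == 0)
    stop("p_offtarget > 0 but no planted integration loci in genome", call. = FALSE)

  cats <- sample(c("concatemer", "off_target", "on_target"), n_reads,
                 replace = TRUE,
                 prob = c(p_concat, p_offtarget, 1 - p_concat - p_offtarget))
  ids <- sprintf("dp_%06d", seq_len(n_reads))
  umis <- vapply(seq_len(n_reads), function(i) random_dna(umi_len), character(1))
  lens <- as.integer(round(runif(n_reads, shear_min, read_len)))
  seqs <- character(n_reads)
  chroms <- rep(NA_character_, n_reads); poss <- rep(NA_integer_, n_reads)
  strands <- rep(NA_character_, n_reads)
  for (i in seq_len(n_reads)) {
    flank_needed <- max(0L, lens[i] - nchar(donor_tail))
    if (cats[i] == "on_target") {
      chrom <- ot$chrom; pos <- ot$cutR_abs; strand <- "+"
      flank <- substr0(genome$seqs[[chrom]], pos, pos + flank_needed)
      chroms[i] <- chrom; poss[i] <- pos; strands[i] <- strand
    } else if (cats[i] == "off_target") {
      j <- sample(nrow(planted), 1L)
      chrom <- planted$chrom[j]; pos <- planted$pos[j]; strand <- planted$strand[j]
      g <- genome$seqs[[chrom]]
      flank <- if (strand == "+") substr0(g, pos, pos + flank_needed)
               else revcomp(substr0(g, max(0L, pos - flank_needed), pos))
      chroms[i] <- chrom; poss[i] <- pos; strands[i] <- strand
    } else {
      # head-to-tail: next copy starts at the donor 5' end;
      # head-to-head: next copy joins end-to-end, i.e. reverse complement
      flank <- if (runif(1) < 0.5) substr0(D, 0L, flank_needed)
               else substr0(revcomp(D), 0L, flank_needed)
    }
    seqs[i] <- substr(paste0(donor_tail, flank), 1L, lens[i])
  }
  reads <- data.frame(id = ids, sequence = seqs,
                      qualities = strrep("I", nchar(seqs)),
                      umi = umis, stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, category = cats, chrom = chroms, pos = poss,
                      strand = strands, umi = umis, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, anchor_primer = anchor_primer,
       donor_tail = donor_tail)
}

#' Simulate a mini-genome with predicted off-target sites and planted
#' integration loci
#'
#' Generates random-sequence chromosomes, optionally embeds a Replace
#' design's target locus, scatters predicted Cas9 off-target sites (as a
#' BED-exportable GRanges), and plants donor integration loci kept at least
#' `min_dist_predicted` bp away from every predicted site, emulating the
#' observed decoupling of integration loci from predicted cleavage sites.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length (>= 10 kb).
#' @param n_offtarget_sites number of predicted Cas9 off-target sites
#'   (default 293, a realistic genome-wide prediction count).
#' @param seed integer seed; output is byte-reproducible given the seed.
#' @param design optional [replace_design()]; its locus is embedded in
#'   chromosome 1 and the absolute cut coordinates recorded.
#' @param n_integration_loci planted off-target donor integration loci
#'   (default 28).
#' @param min_dist_predicted minimum distance (bp) between a planted locus
#'   and any predicted site (default 5100, just beyond the conventional
#'   5000 bp proximity screen).
#' @return a `synthetic_genome` object: `seqs` (named chromosome map),
#'   `predicted` (GRanges), `planted` (data.frame `chrom`, `pos`, `strand`,
#'   `type`), `on_target`, `vector_seq`.
#' @export
simulate_genome <- function(n_chrom = 5L, chrom_len = 1e6L,
                            n_offtarget_sites = 293L, seed = 1L,
                            design = NULL, n_integration_loci = 28L,
                            min_dist_predicted = 5100L) {
  if (chrom_len < 1e4) stop("chromosome length must be >= 10 kb", call. = FALSE)
  with_seed(seed, {
    seqs <- setNames(
      vapply(seq_len(n_chrom), function(i) random_dna(chrom_len), character(1)),
      paste0("chr", seq_len(n_chrom)))
    on_target <- NULL
    vector_seq <- NULL
    locus_lo <- NA_integer_; locus_hi <- NA_integer_
    if (!is.null(design)) {
      locus <- design$locus_seq
      pos <- as.integer(chrom_len %/% 3)
      seqs[["chr1"]] <- paste0(substr0(seqs[["chr1"]], 0L, pos), locus,
                               substr0(seqs[["chr1"]], pos + nchar(locus), chrom_len))
      seqs[["chr1"]] <- substr(seqs[["chr1"]], 1L, chrom_len)
      on_target <- list(chrom = "chr1", locus_start = pos,
                        cutL_abs = pos + design$guide_left$cut,
                        cutR_abs = pos + design$guide_right$cut)
      locus_lo <- pos; locus_hi <- pos + nchar(locus)
      vector_seq <- paste0(design$donor_seq, random_dna(300L))
    }
    margin <- 1000L
    rand_pos <- function(n) {
      chrom <- sample(names(seqs), n, replace = TRUE)
      pos <- as.integer(floor(runif(n, margin, chrom_len - margin)))
      data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    }
    # predicted off-target sites, kept off the embedded locus
    pred <- rand_pos(n_offtarget_sites * 3L)
    near_locus <- pred$chrom == "chr1" & !is.na(locus_lo) &
      pred$pos > locus_lo - 2000L & pred$pos < locus_hi + 2000L
    pred <- utils::head(pred[!near_locus, ], n_offtarget_sites)
    if (nrow(pred) < n_offtarget_sites)
      stop("could not place all predicted off-target sites", call. = FALSE)
    predicted <- GenomicRanges::GRanges(pred$chrom,
      IRanges::IRanges(start = pred$pos + 1L, width = 23L))
    # planted integration loci: rejection-sample away from predicted sites
    planted <- list()
    tries <- 0L
    while (length(planted) < n_integration_loci) {
      tries <- tries + 1L
      if (tries > 200L * n_integration_loci)
        stop("genome too dense to plant integration loci ",
             min_dist_predicted, " bp from all predicted sites", call. = FALSE)
      cand <- rand_pos(1L)
      if (cand$chrom == "chr1" && !is.na(locus_lo) &&
          cand$pos > locus_lo - 2000L && cand$pos < locus_hi + 2000L) next
      same <- pred[pred$chrom == cand$chrom, "pos"]
      if (length(same) && min(abs(same - cand$pos)) < min_dist_predicted) next
      too_close_prev <- any(vapply(planted, function(p)
        p$chrom == cand$chrom && abs(p$pos - cand$pos) < 2000L, logical(1)))
      if (too_close_prev) next
      planted[[length(planted) + 1L]] <-
        list(chrom = cand$chrom, pos = cand$pos,
             strand = sample(c("+", "-"), 1L))
    }
    planted_df <- data.frame(
      chrom = vapply(planted, `[[`, character(1), "chrom"),
      pos = vapply(planted, function(p) as.integer(p$pos), integer(1)),
      strand = vapply(planted, `[[`, character(1), "strand"),
      type = "off_target_integration", stringsAsFactors = FALSE)
    if (!is.null(on_target))
      planted_df <- rbind(planted_df,
        data.frame(chrom = on_target$chrom, pos = on_target$cutR_abs,
                   strand = "+", type = "on_target", stringsAsFactors = FALSE))
    structure(list(seqs = seqs, predicted = predicted, planted = planted_df,
                   on_target = on_target, vector_seq = vector_seq),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chromosomes (%s nt), %d predicted sites, %d planted events\n",
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ","),
              length(x$predicted), nrow(x$planted)))
  invisible(x)
}

#' Write a synthetic genome to FASTA + BED
#'
#' @param genome a [simulate_genome()] object.
#' @param fasta_path,bed_path output paths (FASTA of chromosomes + vector
#'   record, BED of predicted off-target sites).
#' @export
write_genome <- function(genome, fasta_path, bed_path) {
  seqs <- genome$seqs
  if (!is.null(genome$vector_seq)) seqs <- c(seqs, vector = genome$vector_seq)
  write_fasta(seqs, fasta_path)
  write_bed(genome$predicted, bed_path)
  invisible(list(fasta = fasta_path, bed = bed_path))
}
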