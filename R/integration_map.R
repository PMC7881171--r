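#' Check correct donor-anchored priming of a read
#'
#' @param read read sequence.
#' @param donor_primer expected anchor primer at the read 5' end.
#' @param max_mismatch substitutions tolerated (default 2; no InDels).
#' @return logical.
#' @export
check_priming <- function(read, donor_primer, max_mismatch = 2L) {
  plen <- nchar(donor_primer)
  if (nchar(read) < plen) return(FALSE)
  hamming(substr(read, 1L, plen), donor_primer) <= max_mismatch
}

#' Trim a donor-anchored read to the expected break site
#'
#' Locates the donor terminal segment (primer through the donor's ligated
#' end) in the read by alignment, tolerating up to 10% error, and returns
#' everything 3' of it -- the flanking sequence the donor ligated into.
#'
#' @param read read sequence (priming already checked).
#' @param donor_terminal_seq donor sequence from the anchor primer to the
#'   donor's ligated end.
#' @param max_error fraction of the donor terminal segment allowed to
#'   mismatch (default 0.1).
#' @param params alignment scoring.
#' @return the flank string (possibly empty), or `NULL` when the donor
#'   terminal segment is not found within tolerance (read is off-primer).
#' @export
trim_to_break <- function(read, donor_terminal_seq, max_error = 0.1,
                          params = align_params(type = "global-local")) {
  L <- nchar(donor_terminal_seq)
  if (nchar(read) <= L) {
    # read ends inside the donor: accept if what is there matches
    if (hamming(read, substr(donor_terminal_seq, 1L, nchar(read))) <=
        max_error * nchar(read)) return("")
    return(NULL)
  }
  aln <- align_summary(donor_terminal_seq, read, params)
  if (aln$nmatch < (1 - max_error) * L) return(NULL)
  substr0(read, aln$ref_end, nchar(read))
}

# precompiled DNAString index of a chromosome map, built once per library
genome_index <- function(seqs) {
  lapply(seqs, Biostrings::DNAString)
}

# seed-and-extend mapping of a flank against the chromosome map.
# Exact k-mer seed, affine extension, best unique hit wins; score ties at
# distinct loci -> "multi". Position reported is the flank's ligation-
# proximal end (alignment start on +, alignment end on -).
map_flank <- function(flank, seqs, k = 15L, params = align_params(type = "global-local"),
                      min_score_frac = 0.6, tie_margin = 5, index = NULL) {
  n <- nchar(flank)
  if (is.null(index)) index <- genome_index(seqs)
  cands <- list()
  for (orient in c("+", "-")) {
    q <- if (orient == "+") flank else revcomp(flank)
    seed <- substr(q, 1L, k)
    for (chrom in names(seqs)) {
      hits <- BiocGenerics::start(
        Biostrings::matchPattern(seed, index[[chrom]])) - 1L
      for (h in hits) {
        win_lo <- h
        win_hi <- min(nchar(seqs[[chrom]]), h + n + 10L)
        win <- substr0(seqs[[chrom]], win_lo, win_hi)
        if (nchar(win) < k) next
        aln <- align_summary(q, win, params)
        pos <- if (orient == "+") win_lo + aln$ref_start else win_lo + aln$ref_end
        cands[[length(cands) + 1L]] <-
          list(chrom = chrom, pos = pos, strand = orient, score = aln$score)
      }
    }
  }
  if (!length(cands)) return(NULL)
  scores <- vapply(cands, `[[`, numeric(1), "score")
  best <- which.max(scores)
  if (scores[best] < min_score_frac * params$match * n) return(NULL)
  # a tie at a genuinely different locus means the hit is not unique
  for (i in seq_along(cands)) {
    if (i == best) next
    if (scores[i] >= scores[best] - tie_margin &&
        (cands[[i]]$chrom != cands[[best]]$chrom ||
         abs(cands[[i]]$pos - cands[[best]]$pos) > 50L))
      return(list(multi = TRUE))
  }
  cands[[best]]
}

#' Classify the post-donor flank of a donor-anchored read
#'
#' Category logic, in order: a flank whose start matches the donor itself
#' (either orientation, >= 90% identity over the probe) is a concatemer;
#' otherwise the flank is mapped to the genome by exact-seed (k=15) +
#' affine extension and called on-target when within `on_target_window` of
#' either cut, off-target elsewhere; otherwise a flank matching the
#' delivery construct is `vector`; anything left is `unmapped`. The
#' concatemer check precedes genome mapping because donor-derived flanks
#' would otherwise multi-map to the vector record.
#'
#' @param flank flank sequence from [trim_to_break()].
#' @param donor_seq full donor sequence.
#' @param genome a [simulate_genome()] object (or any list with `seqs`,
#'   `on_target`, `vector_seq`).
#' @param on_target_window nt around either cut still counted on-target
#'   (default 1000, absorbing junction resection).
#' @param probe_len nt of flank used for the donor/vector self-match
#'   (default 24).
#' @return list: `category` (`on_target`, `off_target`, `concatemer`,
#'   `vector`, `unmapped`), and `chrom`/`pos`/`strand` for mapped
#'   categories, `reason` otherwise.
#' @export
classify_flank <- function(flank, donor_seq, genome, on_target_window = 1000L,
                           probe_len = 24L, index = NULL) {
  if (is.null(flank) || nchar(flank) < 20L)
    return(list(category = "unmapped", reason = "short"))
  probe <- substr(flank, 1L, min(probe_len, nchar(flank)))
  mm <- as.integer(floor(0.1 * nchar(probe)))
  self_hit <- function(target) {
    length(Biostrings::matchPattern(probe, Biostrings::DNAString(target),
                                    max.mismatch = mm)) > 0
  }
  if (self_hit(donor_seq) || self_hit(revcomp(donor_seq)))
    return(list(category = "concatemer"))
  hit <- map_flank(flank, genome$seqs, index = index)
  if (!is.null(hit) && is.null(hit$multi)) {
    ot <- genome$on_target
    if (!is.null(ot) && hit$chrom == ot$chrom &&
        min(abs(hit$pos - ot$cutL_abs), abs(hit$pos - ot$cutR_abs)) <= on_target_window)
      return(list(category = "on_target", chrom = hit$chrom, pos = hit$pos,
                  strand = hit$strand))
    return(list(category = "off_target", chrom = hit$chrom, pos = hit$pos,
                strand = hit$strand))
  }
  if (!is.null(hit) && isTRUE(hit$multi))
    return(list(category = "unmapped", reason = "multi"))
  if (!is.null(genome$vector_seq) &&
      (self_hit(genome$vector_seq) || self_hit(revcomp(genome$vector_seq))))
    return(list(category = "vector"))
  list(category = "unmapped", reason = "no-hit")
}

#' Map donor integration sites for a whole library
#'
#' Runs priming check, trim-to-break, and flank classification over every
#' read of a donor-anchored library.
#'
#' @param reads data.frame with `id`, `sequence`, optional `umi`.
#' @param donor_primer anchor primer sequence.
#' @param donor_terminal_seq donor segment from primer to ligated end.
#' @param design a [replace_design()] (supplies the donor sequence).
#' @param genome a [simulate_genome()] object.
#' @param ... passed to [classify_flank()].
#' @return data.frame of integration calls: `id`, `category`, `chrom`,
#'   `pos`, `strand`, `flank_len`, `umi`.
#' @export
map_integrations <- function(reads, donor_primer, donor_terminal_seq, design,
                             genome, ...) {
  n <- nrow(reads)
  idx <- genome_index(genome$seqs)
  # distinct flanks are classified once and the calls joined back
  flanks <- rep(NA_character_, n)
  primed <- logical(n)
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    if (!check_priming(s, donor_primer)) next
    primed[i] <- TRUE
    fl <- trim_to_break(s, donor_terminal_seq)
    if (!is.null(fl)) flanks[i] <- fl
  }
  uniq <- unique(flanks[!is.na(flanks)])
  ucalls <- lapply(uniq, function(fl)
    classify_flank(fl, design$donor_seq, genome, index = idx, ...))
  names(ucalls) <- uniq
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    out <- data.frame(id = reads$id[i], category = "off_primer",
                      chrom = NA_character_, pos = NA_integer_,
                      strand = NA_character_, flank_len = NA_integer_,
                      umi = if (is.null(reads$umi)) NA_character_ else reads$umi[i],
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (primed[i] && !is.na(flanks[i])) {
      cl <- ucalls[[flanks[i]]]
      out$flank_len <- nchar(flanks[i])
      out$category <- cl$category
      if (!is.null(cl$chrom)) { out$chrom <- cl$chrom; out$pos <- cl$pos
                                out$strand <- cl$strand }
      if (!is.null(cl$reason)) out$reason <- cl$reason
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}

#' Cluster mapped integration calls into sites
#'
#' Mapped positions within `window` nt are merged into one site
#' ([GenomicRanges::reduce()]); read support is reported with its log10.
#'
#' @param calls integration calls from [map_integrations()].
#' @param window merge distance in nt (default 100).
#' @param categories which call categories enter the site table.
#' @return data.frame: `chrom`, `start`, `end`, `n_reads`, `log10_reads`.
#' @export
cluster_sites <- function(calls, window = 100L,
                          categories = c("on_target", "off_target")) {
  m <- calls[calls$category %in% categories & !is.na(calls$pos), , drop = FALSE]
  if (!nrow(m)) stop("no mapped integration calls to cluster", call. = FALSE)
  gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(start = m$pos + 1L, width = 1L))
  red <- GenomicRanges::reduce(gr, min.gapwidth = window)
  ov <- GenomicRanges::countOverlaps(red, gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = BiocGenerics::start(red) - 1L,
             end = BiocGenerics::end(red),
             n_reads = ov, log10_reads = log10(ov),
             stringsAsFactors = FALSE)
}

#' Annotate integration sites with distance to predicted off-target sites
#'
#' @param sites site table from [cluster_sites()].
#' @param predicted GRanges of predicted Cas9 off-target sites (e.g. from
#'   [read_bed()] or a [simulate_genome()]).
#' @param proximity_bp flag sites at or below this distance (default 5000).
#' @return list: `sites` (table with `nearest_predicted_dist`, Inf when the
#'   chromosome carries no predicted site, and `within_proximity`), and
#'   `summary` (`n_sites`, `n_within_proximity`, `proximity_bp`).
#' @export
offtarget_proximity <- function(sites, predicted, proximity_bp = 5000L) {
  pchroms <- as.character(GenomicRanges::seqnames(predicted))
  unknown <- setdiff(unique(sites$chrom), unique(pchroms))
  if (length(unknown) == length(unique(sites$chrom)))
    stop("chromosome names of sites and predicted BED do not overlap: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dist <- rep(Inf, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- pchroms == sites$chrom[i]
    if (!any(sel)) next
    ps <- BiocGenerics::start(predicted)[sel] - 1L
    pe <- BiocGenerics::end(predicted)[sel]
    # gap between the site interval and each predicted interval
    d <- pmax(0L, pmax(ps - sites$end[i], sites$start[i] - pe))
    dist[i] <- min(d)
  }
  sites$nearest_predicted_dist <- dist
  sites$within_proximity <- dist <= proximity_bp
  list(sites = sites,
       summary = list(n_sites = nrow(sites),
                      n_within_proximity = sum(sites$within_proximity),
                      proximity_bp = proximity_bp))
}
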