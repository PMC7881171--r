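#' Build in-silico expected references for a single-primer library
#'
#' Reconstructs, for every outcome class, the sequence a read anchored at
#' the gene-specific primer would traverse, clipped a fixed distance past
#' the last informative junction so alignment cost stays bounded while
#' still exceeding read length.
#'
#' @param design a [replace_design()].
#' @param anchor_primer primer sequence; must map uniquely to the locus
#'   plus strand, fully upstream of the left cut.
#' @param max_past_junction nt of reference retained beyond the last
#'   junction (default 300).
#' @return named list of references: `klass`, `sequence` (starting with
#'   the anchor primer), `junctions` (positions in reference coordinates).
#' @export
build_expected_references <- function(design, anchor_primer,
                                      max_past_junction = 300L) {
  assert_dna(anchor_primer, "anchor_primer")
  hits <- Biostrings::matchPattern(anchor_primer,
                                   Biostrings::DNAString(design$locus_seq))
  if (length(hits) == 0L) stop("anchor primer not found in locus", call. = FALSE)
  if (length(hits) > 1L) stop("anchor primer is ambiguous in locus (",
                              length(hits), " hits)", call. = FALSE)
  a0 <- BiocGenerics::start(hits)[1] - 1L
  if (a0 + nchar(anchor_primer) > design$guide_left$cut)
    stop("anchor primer must bind fully upstream of the left cut", call. = FALSE)
  cutR <- design$guide_right$cut
  outcomes <- enumerate_outcomes(design)
  lapply(outcomes, function(a) {
    js <- a$junctions
    js$pos <- js$pos - a0
    last <- if (nrow(js)) max(js$pos) else cutR - a0
    clip <- min(nchar(a$sequence) - a0, last + max_past_junction)
    seq <- substr0(a$sequence, a0, a0 + clip)
    js <- js[js$pos <= clip, , drop = FALSE]
    list(klass = a$klass, sequence = seq, junctions = js,
         anchor_primer = anchor_primer)
  })
}

#' Assign single-primer reads to expected references and call junction InDels
#'
#' Reads must begin with the anchor primer (up to 2 substitutions, no
#' InDels); others are discarded with reason `"off-primer"`. Remaining
#' reads are aligned to every reference (read global, reference end-gaps
#' free) and binned by best score with the same ambiguity margin as the
#' long-read classifier; a read that is an exact prefix of exactly one
#' reference is assigned directly. Junction InDels are called only for
#' junctions the read spans by at least `min_junction_overlap` nt on both
#' sides; reads that fall short still count for their class but are
#' excluded from InDel statistics (`j*_covered` = FALSE).
#'
#' @param reads data.frame with `id`, `sequence`, optional `umi`.
#' @param references from [build_expected_references()].
#' @param min_junction_overlap minimum nt of read on each side of a
#'   junction for its InDel call (default 10).
#' @param params alignment scoring; defaults to semi-global
#'   (`type = "global-local"`).
#' @param min_score_margin ambiguity margin as in [classify_reads()].
#' @param junction_window nt around a junction attributed to it.
#' @return data.frame: one row per input read with `klass` (or
#'   `"discarded"` / `"unclassified"`), `reason`, `umi`, per-junction
#'   `j*_covered`, `j*_type`, `j*_size`, `j*_inserted`.
#' @export
assign_and_call <- function(reads, references, min_junction_overlap = 10L,
                            params = align_params(type = "global-local"),
                            min_score_margin = 10, junction_window = 20L) {
  stopifnot(length(references) > 0)
  primer <- references[[1]]$anchor_primer
  plen <- nchar(primer)
  ref_seqs <- vapply(references, `[[`, character(1), "sequence")
  ref_names <- names(references)
  ids <- reads$id
  seqs <- reads$sequence
  umis <- if (is.null(reads$umi)) rep(NA_character_, length(ids)) else reads$umi
  n <- length(seqs)

  prefix <- substr(seqs, 1L, plen)
  on_primer <- nchar(prefix) == plen &
    vapply(prefix, function(p) sum(utf8ToInt(p) != utf8ToInt(primer)) <= 2L, logical(1))

  uniq <- unique(seqs[on_primer])
  nu <- length(uniq)
  u_of <- match(seqs, uniq)

  # exact-prefix shortcut: a read identical to the start of exactly one
  # reference needs no alignment
  pref_hits <- lapply(uniq, function(q)
    which(substr(ref_seqs, 1L, nchar(q)) == q))
  u_best <- rep(NA_integer_, nu); u_score <- rep(NA_real_, nu)
  u_margin <- rep(NA_real_, nu); u_reason <- rep(NA_character_, nu)
  u_aln <- vector("list", nu)
  need <- integer(0)
  for (i in seq_len(nu)) {
    h <- pref_hits[[i]]
    if (length(h) == 1L) {
      u_best[i] <- h; u_score[i] <- params$match * nchar(uniq[i]); u_margin[i] <- Inf
      u_aln[[i]] <- perfect_alignment(uniq[i], ref_names[h], params$match)
    } else if (length(h) > 1L) {
      u_reason[i] <- "ambiguous"  # read ends before references diverge
    } else {
      need <- c(need, i)
    }
  }
  if (length(need)) {
    sc <- matrix(-Inf, length(need), length(ref_seqs))
    for (k in seq_along(ref_seqs))
      sc[, k] <- alignment_scores(uniq[need], ref_seqs[k], params)
    for (j in seq_along(need)) {
      i <- need[j]
      k <- which.max(sc[j, ])
      second <- if (ncol(sc) > 1) max(sc[j, -k]) else -Inf
      u_score[i] <- sc[j, k]
      u_margin[i] <- sc[j, k] - second
      if (u_margin[i] < min_score_margin) u_reason[i] <- "ambiguous"
      else u_best[i] <- k
    }
    for (k in seq_along(ref_seqs)) {
      sel <- need[which(!is.na(u_best[need]) & u_best[need] == k)]
      if (!length(sel)) next
      u_aln[sel] <- align_batch(uniq[sel], ref_seqs[k], params,
                                reference_id = ref_names[k])
    }
  }

  rows <- vector("list", n)
  for (r in seq_len(n)) {
    base <- data.frame(id = ids[r], umi = umis[r], klass = "discarded",
                       reason = "off-primer", score = NA_real_, margin = NA_real_,
                       j1_covered = NA, j1_type = NA_character_,
                       j1_size = NA_integer_, j1_inserted = NA_character_,
                       j2_covered = NA, j2_type = NA_character_,
                       j2_size = NA_integer_, j2_inserted = NA_character_,
                       stringsAsFactors = FALSE)
    if (!on_primer[r]) { rows[[r]] <- base; next }
    i <- u_of[r]
    base$score <- u_score[i]; base$margin <- u_margin[i]
    if (is.na(u_best[i])) {
      base$klass <- "unclassified"; base$reason <- u_reason[i]
      rows[[r]] <- base; next
    }
    k <- u_best[i]
    ref <- references[[k]]
    aln <- u_aln[[i]]
    base$klass <- ref$klass; base$reason <- NA_character_
    js <- ref$junctions
    for (j in seq_len(min(2L, nrow(js)))) {
      jpos <- js$pos[j]
      covered <- aln$ref_start + min_junction_overlap <= jpos &&
        aln$ref_end - min_junction_overlap >= jpos
      base[[paste0("j", j, "_covered")]] <- covered
      if (covered) {
        jc <- junction_call_from_ops(aln$ops, aln$query, jpos, junction_window)
        base[[paste0("j", j, "_type")]] <- jc$type
        base[[paste0("j", j, "_size")]] <- jc$size
        base[[paste0("j", j, "_inserted")]] <- jc$inserted
      }
    }
    rows[[r]] <- base
  }
  do.call(rbind, rows)
}

#' Tally unique molecules per outcome class
#'
#' Molecules are distinct UMIs; a UMI observed with conflicting classes is
#' resolved by strict majority and discarded on a tie. When no reads carry
#' UMIs the tally falls back to read counting with a warning (LAM
#' libraries carry no UMIs).
#'
#' @param assignments from [assign_and_call()].
#' @return an object of class `outcome_table`: `table` (per class:
#'   `n_molecules`, `fraction` over counted molecules), `indels`
#'   (per class and junction: InDel type breakdown over molecules with
#'   that junction covered), `n_molecules`, `umi_mode`,
#'   `n_conflict_discarded`, and read-accounting counts.
#' @export
tally_umis <- function(assignments) {
  a <- assignments
  counted <- a[!a$klass %in% c("discarded", "unclassified"), , drop = FALSE]
  umi_mode <- any(!is.na(counted$umi))
  if (!umi_mode) {
    warning("no UMIs present; falling back to read-level counting")
    counted$umi <- counted$id  # every read its own molecule
  }
  n_conflict <- 0L
  reps <- list()
  for (u in unique(counted$umi)) {
    grp <- counted[counted$umi == u, , drop = FALSE]
    tab <- sort(table(grp$klass), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) { n_conflict <- n_conflict + 1L; next }
    reps[[length(reps) + 1L]] <- grp[grp$klass == names(tab)[1], , drop = FALSE][1, ]
  }
  mols <- do.call(rbind, reps)
  if (is.null(mols) || !nrow(mols)) stop("no countable molecules", call. = FALSE)
  tab <- as.data.frame(table(klass = mols$klass), stringsAsFactors = FALSE)
  names(tab)[2] <- "n_molecules"
  tab$fraction <- tab$n_molecules / sum(tab$n_molecules)
  tab <- tab[order(match(tab$klass, OUTCOME_CLASSES)), ]
  rownames(tab) <- NULL
  ind <- list()
  for (j in 1:2) {
    cov <- mols[[paste0("j", j, "_covered")]]
    sel <- mols[!is.na(cov) & cov, , drop = FALSE]
    if (!nrow(sel)) next
    d <- as.data.frame(table(klass = sel$klass,
                             type = sel[[paste0("j", j, "_type")]]),
                       stringsAsFactors = FALSE)
    d <- d[d$Freq > 0, , drop = FALSE]
    d$junction <- j
    ind[[length(ind) + 1L]] <- d
  }
  indels <- if (length(ind)) do.call(rbind, ind) else
    data.frame(klass = character(0), type = character(0), Freq = integer(0),
               junction = integer(0))
  structure(list(table = tab, indels = indels,
                 n_molecules = sum(tab$n_molecules), umi_mode = umi_mode,
                 n_conflict_discarded = n_conflict,
                 n_reads = nrow(a),
                 n_discarded = sum(a$klass == "discarded"),
                 n_unclassified = sum(a$klass == "unclassified"),
                 n_assigned = nrow(counted)),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("outcome_table: %d molecules (%s), %d reads (%d discarded, %d unclassified)\n",
              x$n_molecules, if (x$umi_mode) "unique UMIs" else "read-level",
              x$n_reads, x$n_discarded, x$n_unclassified))
  print(x$table)
  invisible(x)
}

#' Report the quantified editing outcomes of a single-primer library
#'
#' Per-class molecule fractions, the fwd:rev orientation ratio of each
#' donor-bearing class pair, and the InDel-free fraction per junction.
#'
#' @param table an [tally_umis()] `outcome_table`.
#' @return list (JSON-serializable) with `fractions`, `fwd_rev_ratio`,
#'   `indelfree`, and molecule/read accounting.
#' @export
outcome_report <- function(table) {
  stopifnot(inherits(table, "outcome_table"))
  tab <- table$table
  fractions <- setNames(as.list(tab$fraction), tab$klass)
  ratios <- list()
  for (b in c("replacement", "insertion_up", "insertion_down")) {
    nf <- tab$n_molecules[tab$klass == paste0(b, "_fwd")]
    nr <- tab$n_molecules[tab$klass == paste0(b, "_rev")]
    nf <- if (length(nf)) nf else 0L
    nr <- if (length(nr)) nr else 0L
    if (nf + nr > 0)
      ratios[[b]] <- list(fwd = nf, rev = nr,
                          ratio = if (nr > 0) nf / nr else Inf,
                          fwd_fraction = nf / (nf + nr))
  }
  indelfree <- list()
  ind <- table$indels
  for (k in unique(ind$klass)) {
    for (j in unique(ind$junction[ind$klass == k])) {
      sel <- ind[ind$klass == k & ind$junction == j, ]
      tot <- sum(sel$Freq)
      none <- sum(sel$Freq[sel$type == "none"])
      indelfree[[paste0(k, "_j", j)]] <-
        list(fraction = none / tot, n_indelfree = none, n_total = tot)
    }
  }
  list(fractions = fractions, fwd_rev_ratio = ratios, indelfree = indelfree,
       n_molecules = table$n_molecules, umi_mode = table$umi_mode,
       n_reads = table$n_reads, n_discarded = table$n_discarded,
       n_unclassified = table$n_unclassified,
       n_conflict_discarded = table$n_conflict_discarded)
}
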