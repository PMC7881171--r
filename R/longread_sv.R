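#' Expected amplicons for every outcome class
#'
#' Builds the full two-primer amplicon of each enumerated outcome allele,
#' with junction coordinates shifted into amplicon space. These are the
#' references the long-read classifier bins reads against.
#'
#' @param design a [replace_design()].
#' @param primer_left_offset,primer_right_offset primer footprints as in
#'   [simulate_longread()].
#' @return named list per outcome class: `klass`, `sequence`, `junctions`.
#' @export
expected_amplicons <- function(design, primer_left_offset = 50L,
                               primer_right_offset = 50L) {
  outcomes <- enumerate_outcomes(design)
  lapply(outcomes, function(a) {
    seq <- substr0(a$sequence, primer_left_offset,
                   nchar(a$sequence) - primer_right_offset)
    js <- a$junctions
    js$pos <- js$pos - primer_left_offset
    list(klass = a$klass, sequence = seq, junctions = js)
  })
}

donor_bearing <- function(klass) grepl("^(replacement|insertion)", klass)

orientation_of <- function(klass) {
  ifelse(grepl("_fwd$", klass), "fwd",
         ifelse(grepl("_rev$", klass), "rev", "n/a"))
}

# summarise indel ops overlapping one junction window
junction_call_from_ops <- function(ops, query, jpos, window) {
  lo <- jpos - window; hi <- jpos + window
  idx <- which(ops$op %in% c("insertion", "deletion"))
  out <- list(type = "none", size = 0L, inserted = NA_character_)
  if (!length(idx)) return(out)
  sel <- integer(0)
  for (i in idx) {
    op_lo <- ops$ref_start[i]
    op_hi <- if (ops$op[i] == "deletion") ops$ref_start[i] + ops$length[i] else ops$ref_start[i]
    # an indel overlaps the window if any part of it (insertions are points
    # on the reference) falls inside [lo, hi]
    if (op_hi >= lo && op_lo <= hi) sel <- c(sel, i)
  }
  if (!length(sel)) return(out)
  kinds <- unique(ops$op[sel])
  out$type <- if (length(kinds) == 2L) "complex" else
    if (kinds == "insertion") "insertion" else "deletion"
  out$size <- sum(ops$length[sel])
  ins_sel <- sel[ops$op[sel] == "insertion"]
  if (length(ins_sel)) {
    out$inserted <- paste(vapply(ins_sel, function(i)
      substr(query, ops$query_start[i] + 1L, ops$query_start[i] + ops$length[i]),
      character(1)), collapse = "")
  }
  out
}

perfect_alignment <- function(seq, reference_id, match_score = 2) {
  n <- nchar(seq)
  pair_alignment(data.frame(op = "match", length = n, ref_start = 0L,
                            query_start = 0L, stringsAsFactors = FALSE),
                 score = match_score * n, ref_start = 0L, ref_end = n,
                 query = seq, reference_id = reference_id)
}

#' Classify long-read amplicons into structural-variant classes
#'
#' Each read (and its reverse complement) is aligned to the expected
#' amplicon of every outcome class; the best-scoring reference assigns the
#' class and donor orientation. Calls whose best and runner-up references
#' (of different class) score within `min_score_margin` are reported
#' `unclassified` rather than arbitrarily assigned. InDels within
#' `junction_window` nt of each expected junction (overlap in any part
#' counts) are summarised per junction.
#'
#' @param reads data.frame with `id` and `sequence` (e.g. from
#'   [simulate_longread()] or [read_fastq()]).
#' @param expected references from [expected_amplicons()].
#' @param params alignment scoring ([align_params()]).
#' @param min_score_margin minimum best-vs-runner-up score separation.
#' @param junction_window nt around each junction attributed to it.
#' @param large_del_threshold junction deletions above this are flagged
#'   `large_deletion` (default 500 bp).
#' @param min_read_frac reads shorter than this fraction of the shortest
#'   expected amplicon are unclassified with reason `"short"`.
#' @return an object of class `structural_calls`: `calls` data.frame (one
#'   row per read: `klass`, `orientation`, `read_strand`, per-junction
#'   InDel columns, `large_deletion`, `reason`), `alignments` (named list
#'   of `pair_alignment` against the assigned reference), `expected`.
#' @export
classify_reads <- function(reads, expected, params = align_params(type = "global"),
                           min_score_margin = 10, junction_window = 20L,
                           large_del_threshold = 500L, min_read_frac = 0.5) {
  stopifnot(length(expected) > 0)
  ref_seqs <- vapply(expected, `[[`, character(1), "sequence")
  ref_names <- names(expected)
  min_ref <- min(nchar(ref_seqs))
  seqs <- reads$sequence
  ids <- reads$id
  n <- length(seqs)

  uniq <- unique(seqs)
  u_of <- match(seqs, uniq)
  nu <- length(uniq)
  uniq_rc <- revcomp(uniq)

  # score matrix over references x orientations, on unique sequences only
  too_short <- nchar(uniq) < min_read_frac * min_ref
  sc_fwd <- matrix(-Inf, nu, length(ref_seqs))
  sc_rev <- matrix(-Inf, nu, length(ref_seqs))
  # exact matches bypass alignment entirely
  exact_fwd <- match(uniq, ref_seqs)
  exact_rev <- match(uniq_rc, ref_seqs)
  need <- which(!too_short & is.na(exact_fwd) & is.na(exact_rev))
  for (k in seq_along(ref_seqs)) {
    if (length(need)) {
      sc_fwd[need, k] <- alignment_scores(uniq[need], ref_seqs[k], params)
      sc_rev[need, k] <- alignment_scores(uniq_rc[need], ref_seqs[k], params)
    }
  }

  u_best_ref <- integer(nu); u_strand <- character(nu)
  u_margin <- numeric(nu); u_score <- numeric(nu); u_reason <- rep(NA_character_, nu)
  for (i in seq_len(nu)) {
    if (too_short[i]) { u_best_ref[i] <- NA; u_reason[i] <- "short"; next }
    if (!is.na(exact_fwd[i]) || !is.na(exact_rev[i])) {
      u_best_ref[i] <- if (!is.na(exact_fwd[i])) exact_fwd[i] else exact_rev[i]
      u_strand[i] <- if (!is.na(exact_fwd[i])) "+" else "-"
      u_score[i] <- params$match * nchar(uniq[i])
      u_margin[i] <- Inf
      next
    }
    best_per_ref <- pmax(sc_fwd[i, ], sc_rev[i, ])
    k <- which.max(best_per_ref)
    second <- if (length(best_per_ref) > 1) max(best_per_ref[-k]) else -Inf
    u_score[i] <- best_per_ref[k]
    u_margin[i] <- best_per_ref[k] - second
    if (u_margin[i] < min_score_margin) {
      u_best_ref[i] <- NA; u_reason[i] <- "ambiguous"
    } else {
      u_best_ref[i] <- k
      u_strand[i] <- if (sc_fwd[i, k] >= sc_rev[i, k]) "+" else "-"
    }
  }

  # full alignments, batched per assigned reference
  u_aln <- vector("list", nu)
  for (k in seq_along(ref_seqs)) {
    sel <- which(!is.na(u_best_ref) & u_best_ref == k)
    if (!length(sel)) next
    qs <- ifelse(u_strand[sel] == "+", uniq[sel], uniq_rc[sel])
    is_exact <- qs == ref_seqs[k]
    if (any(is_exact)) {
      for (i in sel[is_exact])
        u_aln[[i]] <- perfect_alignment(ref_seqs[k], ref_names[k], params$match)
    }
    if (any(!is_exact)) {
      alns <- align_batch(qs[!is_exact], ref_seqs[k], params,
                          reference_id = ref_names[k])
      u_aln[sel[!is_exact]] <- alns
    }
  }

  # per-read call table
  rows <- vector("list", n)
  alignments <- vector("list", n)
  for (r in seq_len(n)) {
    i <- u_of[r]
    if (is.na(u_best_ref[i])) {
      rows[[r]] <- data.frame(id = ids[r], klass = "unclassified",
                              orientation = "n/a", read_strand = NA_character_,
                              score = u_score[i], margin = u_margin[i],
                              j1_type = NA_character_, j1_size = NA_integer_,
                              j1_inserted = NA_character_,
                              j2_type = NA_character_, j2_size = NA_integer_,
                              j2_inserted = NA_character_,
                              large_deletion = NA, reason = u_reason[i],
                              stringsAsFactors = FALSE)
      next
    }
    k <- u_best_ref[i]
    ref <- expected[[k]]
    aln <- u_aln[[i]]
    alignments[[r]] <- aln
    jcalls <- lapply(seq_len(min(2L, nrow(ref$junctions))), function(j)
      junction_call_from_ops(aln$ops, aln$query, ref$junctions$pos[j],
                             junction_window))
    pad <- function(j, f, default) if (length(jcalls) >= j) jcalls[[j]][[f]] else default
    big <- any(vapply(jcalls, function(jc)
      jc$type %in% c("deletion", "complex") && jc$size > large_del_threshold,
      logical(1)))
    rows[[r]] <- data.frame(id = ids[r], klass = ref$klass,
                            orientation = orientation_of(ref$klass),
                            read_strand = u_strand[i],
                            score = u_score[i], margin = u_margin[i],
                            j1_type = pad(1, "type", NA_character_),
                            j1_size = pad(1, "size", NA_integer_),
                            j1_inserted = pad(1, "inserted", NA_character_),
                            j2_type = pad(2, "type", NA_character_),
                            j2_size = pad(2, "size", NA_integer_),
                            j2_inserted = pad(2, "inserted", NA_character_),
                            large_deletion = big, reason = NA_character_,
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  names(alignments) <- ids
  structure(list(calls = calls, alignments = alignments, expected = expected),
            class = "structural_calls")
}

#' Classify a single read
#'
#' Convenience wrapper around [classify_reads()] for one sequence.
#'
#' @param read a DNA string, or a one-row data.frame with `id`, `sequence`.
#' @param expected references from [expected_amplicons()].
#' @param ... passed to [classify_reads()].
#' @return one-row `calls` data.frame.
#' @export
classify_read <- function(read, expected, ...) {
  if (is.character(read)) read <- data.frame(id = "read_1", sequence = read,
                                             stringsAsFactors = FALSE)
  classify_reads(read, expected, ...)$calls
}

#' @export
print.structural_calls <- function(x, ...) {
  tab <- table(x$calls$klass)
  cat("structural_calls:", nrow(x$calls), "reads\n")
  print(tab)
  invisible(x)
}

#' Class-by-orientation summary of structural calls
#'
#' Fractions over classified reads; donor-bearing classes additionally get
#' the fwd/rev split within their class pair (the directionality readout of
#' a Replace experiment).
#'
#' @param x a `structural_calls` object or its `calls` data.frame.
#' @return data.frame with `klass`, `orientation`, `n`,
#'   `fraction_classified` (of all classified reads) and
#'   `fraction_within_pair` (fwd/rev split within a donor-bearing class
#'   pair; NA for original/deletion). When no donor-bearing reads are
#'   present the attribute `no_donor_classes` is set to TRUE.
#' @export
orientation_summary <- function(x) {
  calls <- if (inherits(x, "structural_calls")) x$calls else x
  if (!nrow(calls)) stop("no calls", call. = FALSE)
  cl <- calls[calls$klass != "unclassified", ]
  if (!nrow(cl)) stop("no classified reads", call. = FALSE)
  tab <- as.data.frame(table(klass = cl$klass), stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab$orientation <- orientation_of(tab$klass)
  tab$fraction_classified <- tab$n / sum(tab$n)
  base <- sub("_(fwd|rev)$", "", tab$klass)
  tab$fraction_within_pair <- NA_real_
  for (b in unique(base[donor_bearing(tab$klass)])) {
    sel <- base == b
    tab$fraction_within_pair[sel] <- tab$n[sel] / sum(tab$n[sel])
  }
  tab <- tab[order(match(tab$klass, OUTCOME_CLASSES)),
             c("klass", "orientation", "n", "fraction_classified",
               "fraction_within_pair")]
  rownames(tab) <- NULL
  if (!any(donor_bearing(tab$klass))) attr(tab, "no_donor_classes") <- TRUE
  tab
}

#' Per-base deletion profile over a reference amplicon
#'
#' For reads assigned to one outcome class, the fraction of reads carrying
#' a deletion at each base of that class's expected amplicon: position i is
#' (#reads whose alignment covers i with a deletion) / (#reads covering i).
#' Positions covered by no read are reported NA, not 0.
#'
#' @param x a `structural_calls` object.
#' @param reference_klass outcome class whose amplicon frames the profile.
#' @return data.frame with `pos` (0-based), `coverage`, `deleted`,
#'   `fraction`.
#' @export
deletion_profile <- function(x, reference_klass) {
  stopifnot(inherits(x, "structural_calls"))
  sel <- which(x$calls$klass == reference_klass)
  if (!length(sel)) stop("no reads assigned to class ", reference_klass, call. = FALSE)
  ref_len <- nchar(x$expected[[reference_klass]]$sequence)
  cov <- integer(ref_len); del <- integer(ref_len)
  for (r in sel) {
    aln <- x$alignments[[r]]
    if (is.null(aln)) next
    lo <- aln$ref_start + 1L; hi <- aln$ref_end
    cov[lo:hi] <- cov[lo:hi] + 1L
    dops <- aln$ops[aln$ops$op == "deletion", , drop = FALSE]
    for (i in seq_len(nrow(dops))) {
      a <- dops$ref_start[i] + 1L
      b <- dops$ref_start[i] + dops$length[i]
      del[a:b] <- del[a:b] + 1L
    }
  }
  data.frame(pos = seq_len(ref_len) - 1L, coverage = cov, deleted = del,
             fraction = ifelse(cov > 0, del / cov, NA_real_))
}

#' InDel-free fraction at one junction of one outcome class
#'
#' The fraction of reads of a class whose ligated junction carries no
#' insertion or deletion -- the fidelity readout of NHEJ ligation.
#'
#' @param x a `structural_calls` object or `calls` data.frame.
#' @param klass outcome class.
#' @param junction_index 1-based junction index within that class.
#' @return list with `fraction`, `n_indelfree`, `n_total`.
#' @export
junction_indelfree_fraction <- function(x, klass, junction_index) {
  calls <- if (inherits(x, "structural_calls")) x$calls else x
  sel <- calls[calls$klass == klass, , drop = FALSE]
  if (!nrow(sel)) stop("no calls of class ", klass, call. = FALSE)
  n_j <- sum(!is.na(sel[1, c("j1_type", "j2_type")]))
  if (n_j == 0L) stop("class ", klass, " has no junctions", call. = FALSE)
  if (junction_index < 1 || junction_index > n_j)
    stop("junction_index out of range; valid indices: ",
         paste(seq_len(n_j), collapse = ", "), call. = FALSE)
  types <- sel[[paste0("j", junction_index, "_type")]]
  list(fraction = mean(types == "none"),
       n_indelfree = sum(types == "none"),
       n_total = length(types))
}
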