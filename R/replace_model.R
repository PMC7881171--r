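#' @name replace_model
#' @title Data model for a two-cut Replace editing experiment
#'
#' @description
#' Replace editing excises a genomic segment between two Cas9 cuts and
#' ligates a donor sequence in its place by non-homologous end joining.
#' This module holds the experiment geometry (locus, two guide sites,
#' donor), enumerates the eight post-editing allele structures that perfect
#' cut-and-ligate repair can produce, and validates the directional design
#' principle: junctions of undesired products reform a Cas9 target site and
#' are re-cut, while correct donor integration disrupts the target site.
#'
#' All coordinates are 0-based; cut positions are inter-base. The canonical
#' SpyCas9 blunt cut falls between protospacer positions 17 and 18, i.e.
#' 3 nt from the PAM-proximal protospacer end.
NULL

OUTCOME_CLASSES <- c("original", "deletion", "replacement_fwd", "replacement_rev",
                     "insertion_up_fwd", "insertion_up_rev",
                     "insertion_down_fwd", "insertion_down_rev")

SIDE_PAM   <- "PAM-proximal"
SIDE_PROTO <- "protospacer-side"

#' Construct a guide site
#'
#' @param protospacer 20-nt protospacer (always given 5'->3' in protospacer
#'   sense, i.e. as the gRNA spacer reads).
#' @param pam 3-nt PAM (NGG for SpyCas9).
#' @param strand `"+"` or `"-"`: strand of the reference carrying the
#'   protospacer.
#' @param start 0-based offset of the protospacer on the reference. On the
#'   minus strand this is the offset of the leftmost reference base covered
#'   by the protospacer.
#' @return an object of class `guide_site` with the inter-base `cut`
#'   coordinate filled in (`start + 17` on `+`, `start + 3` on `-`).
#' @export
guide_site <- function(protospacer, pam, strand, start) {
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20) stop("protospacer must be exactly 20 nt", call. = FALSE)
  if (!grepl("^[ACGT]GG$", pam)) stop("PAM must match NGG", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  start <- as.integer(start)
  cut <- if (strand == "+") start + 17L else start + 3L
  structure(list(protospacer = protospacer, pam = pam, strand = strand,
                 start = start, cut = cut),
            class = "guide_site")
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("guide_site %s %s strand %s start %d cut %d\n",
              x$protospacer, x$pam, x$strand, x$start, x$cut))
  invisible(x)
}

#' Locate all SpyCas9 target sites of a protospacer in a locus
#'
#' Scans both strands for the exact protospacer followed by an NGG PAM.
#'
#' @param locus_seq reference sequence (character).
#' @param protospacer 20-nt protospacer.
#' @return list of [guide_site()] objects in coordinate order; empty list if
#'   the protospacer targets nowhere.
#' @export
locate_guide <- function(locus_seq, protospacer) {
  assert_dna(locus_seq, "locus_seq")
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20) stop("protospacer must be exactly 20 nt", call. = FALSE)
  hits <- list()
  n <- nchar(locus_seq)
  # plus strand: protospacer at [s, s+20), PAM at [s+20, s+23)
  plus <- Biostrings::matchPattern(protospacer, Biostrings::DNAString(locus_seq))
  for (s in BiocGenerics::start(plus) - 1L) {
    pam <- substr0(locus_seq, s + 20L, s + 23L)
    if (grepl("^[ACGT]GG$", pam))
      hits[[length(hits) + 1L]] <- guide_site(protospacer, pam, "+", s)
  }
  # minus strand: protospacer occupies [s, s+20) as its reverse complement,
  # PAM occupies [s-3, s) as the reverse complement of NGG (CCN)
  minus <- Biostrings::matchPattern(revcomp(protospacer), Biostrings::DNAString(locus_seq))
  for (s in BiocGenerics::start(minus) - 1L) {
    if (s < 3L) next
    pam_rc <- substr0(locus_seq, s - 3L, s)
    if (grepl("^CC[ACGT]$", pam_rc))
      hits[[length(hits) + 1L]] <- guide_site(protospacer, revcomp(pam_rc), "-", s)
  }
  hits[order(vapply(hits, `[[`, integer(1), "start"))]
}

# one physical fragment end: which side of the Cas9 break it is, and the
# guide (protospacer + orientation on the current sequence) that formed it
junction_side <- function(label, protospacer, strand) {
  list(label = label, protospacer = protospacer, strand = strand)
}

# label of the sequence left/right of a guide's cut (plus-strand guide: PAM
# lies right of the cut; minus-strand guide: PAM lies left of it)
side_left_of_cut  <- function(g) if (g$strand == "+") SIDE_PROTO else SIDE_PAM
side_right_of_cut <- function(g) if (g$strand == "+") SIDE_PAM else SIDE_PROTO

flip_side <- function(s) {
  s$strand <- if (s$strand == "+") "-" else "+"
  s
}

#' Construct a Replace design
#'
#' @param locus_seq reference locus sequence.
#' @param guide_left,guide_right [guide_site()] objects with
#'   `guide_left$cut < guide_right$cut`; both must occur in `locus_seq`.
#' @param donor_seq donor sequence, 5'->3' in its designed ("fwd")
#'   orientation.
#' @param donor_left_side,donor_right_side which side of a Cas9 break each
#'   donor end reconstitutes: `"PAM-proximal"` or `"protospacer-side"`.
#' @param donor_left_guide,donor_right_guide optional: the guide that
#'   linearized each donor end, as `list(protospacer=, strand=)` with strand
#'   giving the protospacer orientation within the fwd donor. Needed only
#'   for the staggered-cut insertion model at donor-derived junction sides.
#' @param buffer_left,buffer_right nt of sacrificial buffer inside each
#'   donor end.
#' @param extra_guides optional character vector of additional 20-nt
#'   protospacers available for re-cutting undesired junctions.
#' @return an object of class `replace_design`.
#' @export
replace_design <- function(locus_seq, guide_left, guide_right, donor_seq,
                           donor_left_side = SIDE_PROTO,
                           donor_right_side = SIDE_PAM,
                           donor_left_guide = NULL, donor_right_guide = NULL,
                           buffer_left = 0L, buffer_right = 0L,
                           extra_guides = character()) {
  assert_dna(locus_seq, "locus_seq")
  assert_dna(donor_seq, "donor_seq")
  stopifnot(inherits(guide_left, "guide_site"), inherits(guide_right, "guide_site"))
  if (guide_left$cut >= guide_right$cut)
    stop("guide cuts must be distinct with guide_left$cut < guide_right$cut",
         call. = FALSE)
  for (g in list(guide_left, guide_right)) {
    found <- locate_guide(locus_seq, g$protospacer)
    if (!any(vapply(found, function(h) h$start == g$start && h$strand == g$strand,
                    logical(1))))
      stop("guide ", g$protospacer, " not found at start=", g$start,
           " strand=", g$strand, " in locus", call. = FALSE)
  }
  if (buffer_left < 0 || buffer_right < 0) stop("buffers must be >= 0", call. = FALSE)
  if (guide_right$cut - guide_left$cut < 40)
    warning("cuts are < 40 nt apart; fine for toy inputs, unrealistic for a real design")
  if (nchar(donor_seq) < 50)
    warning("donor is < 50 nt; fine for toy inputs, unrealistic for a real design")
  side_chk <- c(donor_left_side, donor_right_side) %in% c(SIDE_PAM, SIDE_PROTO)
  if (!all(side_chk)) stop("donor junction sides must be '", SIDE_PAM,
                           "' or '", SIDE_PROTO, "'", call. = FALSE)
  d_left <- junction_side(donor_left_side,
                          if (is.null(donor_left_guide)) NA_character_ else donor_left_guide$protospacer,
                          if (is.null(donor_left_guide)) "+" else donor_left_guide$strand)
  d_right <- junction_side(donor_right_side,
                           if (is.null(donor_right_guide)) NA_character_ else donor_right_guide$protospacer,
                           if (is.null(donor_right_guide)) "+" else donor_right_guide$strand)
  structure(list(locus_seq = locus_seq, guide_left = guide_left,
                 guide_right = guide_right, donor_seq = donor_seq,
                 donor_end_left = d_left, donor_end_right = d_right,
                 buffer_left = as.integer(buffer_left),
                 buffer_right = as.integer(buffer_right),
                 extra_guides = extra_guides),
            class = "replace_design")
}

#' @export
print.replace_design <- function(x, ...) {
  cat(sprintf(paste0("replace_design: locus %d nt, cuts at %d/%d ",
                     "(excised %d nt), donor %d nt, buffers %d/%d nt\n"),
              nchar(x$locus_seq), x$guide_left$cut, x$guide_right$cut,
              x$guide_right$cut - x$guide_left$cut, nchar(x$donor_seq),
              x$buffer_left, x$buffer_right))
  invisible(x)
}

# junction table row constructor
junction_row <- function(pos, left, right) {
  data.frame(pos = as.integer(pos),
             left_label = left$label, right_label = right$label,
             left_protospacer = left$protospacer, left_strand = left$strand,
             right_protospacer = right$protospacer, right_strand = right$strand,
             stringsAsFactors = FALSE)
}

empty_junctions <- function() junction_row(integer(0), junction_side(character(0), character(0), character(0)),
                                           junction_side(character(0), character(0), character(0)))

outcome_allele <- function(klass, sequence, junctions) {
  structure(list(klass = klass, sequence = sequence, junctions = junctions),
            class = "outcome_allele")
}

#' @export
print.outcome_allele <- function(x, ...) {
  cat(sprintf("outcome_allele %s: %d nt, %d junction(s)\n",
              x$klass, nchar(x$sequence), nrow(x$junctions)))
  invisible(x)
}

#' Enumerate all expected post-editing allele structures
#'
#' Builds the eight perfect cut-and-ligate products of a two-cut + donor
#' experiment: the unedited original; the deletion (outer fragments
#' religated); donor replacement in designed and inverted orientation; and
#' donor insertion at either cut, in either orientation, with the excised
#' segment retained. Junction coordinates and break-side labels (which side
#' of a Cas9 break each ligated end derives from) are populated on every
#' allele; these labels drive the staggered-cut insertion model downstream.
#'
#' @param design a [replace_design()].
#' @return named list of 8 `outcome_allele` objects, in canonical class
#'   order (`original`, `deletion`, `replacement_fwd`, `replacement_rev`,
#'   `insertion_up_fwd`, `insertion_up_rev`, `insertion_down_fwd`,
#'   `insertion_down_rev`).
#' @export
enumerate_outcomes <- function(design) {
  stopifnot(inherits(design, "replace_design"))
  cutL <- design$guide_left$cut
  cutR <- design$guide_right$cut
  if (cutL == cutR) stop("the two cuts coincide", call. = FALSE)
  L <- design$locus_seq
  l <- substr0(L, 0L, cutL)
  m <- substr0(L, cutL, cutR)
  r <- substr0(L, cutR, nchar(L))
  D <- design$donor_seq
  Drc <- revcomp(D)
  gL <- design$guide_left; gR <- design$guide_right

  end_l   <- junction_side(side_left_of_cut(gL), gL$protospacer, gL$strand)
  start_m <- junction_side(side_right_of_cut(gL), gL$protospacer, gL$strand)
  end_m   <- junction_side(side_left_of_cut(gR), gR$protospacer, gR$strand)
  start_r <- junction_side(side_right_of_cut(gR), gR$protospacer, gR$strand)
  d_start <- design$donor_end_left
  d_end   <- design$donor_end_right
  # reverse-complementing the donor swaps its ends and flips their strands
  d_start_rev <- flip_side(d_end)
  d_end_rev   <- flip_side(d_start)

  nl <- nchar(l); nm <- nchar(m); nD <- nchar(D)
  out <- list(
    original = outcome_allele("original", L, empty_junctions()),
    deletion = outcome_allele("deletion", paste0(l, r),
                              junction_row(nl, end_l, start_r)),
    replacement_fwd = outcome_allele("replacement_fwd", paste0(l, D, r),
      rbind(junction_row(nl, end_l, d_start),
            junction_row(nl + nD, d_end, start_r))),
    replacement_rev = outcome_allele("replacement_rev", paste0(l, Drc, r),
      rbind(junction_row(nl, end_l, d_start_rev),
            junction_row(nl + nD, d_end_rev, start_r))),
    insertion_up_fwd = outcome_allele("insertion_up_fwd", paste0(l, D, m, r),
      rbind(junction_row(nl, end_l, d_start),
            junction_row(nl + nD, d_end, start_m))),
    insertion_up_rev = outcome_allele("insertion_up_rev", paste0(l, Drc, m, r),
      rbind(junction_row(nl, end_l, d_start_rev),
            junction_row(nl + nD, d_end_rev, start_m))),
    insertion_down_fwd = outcome_allele("insertion_down_fwd", paste0(l, m, D, r),
      rbind(junction_row(nl + nm, end_m, d_start),
            junction_row(nl + nm + nD, d_end, start_r))),
    insertion_down_rev = outcome_allele("insertion_down_rev", paste0(l, m, Drc, r),
      rbind(junction_row(nl + nm, end_m, d_start_rev),
            junction_row(nl + nm + nD, d_end_rev, start_r)))
  )
  out
}

#' Is a ligated junction re-cleavable by any supplied guide?
#'
#' A junction is re-cleavable when a window around it contains an intact
#' protospacer followed by an NGG PAM, on either strand, for any of the
#' supplied guides. In a directional design, junctions of undesired
#' products (deletion, inverted donor) reform a target site and are re-cut,
#' while correct integration disrupts it.
#'
#' @param sequence allele sequence.
#' @param junction_pos 0-based inter-base junction coordinate.
#' @param guides character vector of 20-nt protospacers.
#' @param window nt scanned on each side of the junction (default 30,
#'   covering protospacer + PAM plus staggered-cut remnants).
#' @return logical.
#' @export
junction_recleavable <- function(sequence, junction_pos, guides, window = 30L) {
  assert_dna(sequence, "sequence")
  if (junction_pos < 0 || junction_pos > nchar(sequence))
    stop("junction_pos outside sequence", call. = FALSE)
  lo <- max(0L, junction_pos - window)
  hi <- min(nchar(sequence), junction_pos + window)
  win <- substr0(sequence, lo, hi)
  win_rc <- revcomp(win)
  for (p in guides) {
    pat <- paste0(p, "[ACGT]GG")
    if (grepl(pat, win) || grepl(pat, win_rc)) return(TRUE)
  }
  FALSE
}

#' Validate the directional design principles of a Replace experiment
#'
#' Checks that correct donor integration (`replacement_fwd`) disrupts every
#' Cas9 target site while the deletion and inverted-donor junctions reform
#' one (so those products are re-cut and recycled), that sacrificial
#' buffers meet the recommended minimum, and counts the distinct guides the
#' design uses.
#'
#' @param design a [replace_design()].
#' @param min_buffer minimum sacrificial buffer per donor end (default 30
#'   nt, absorbing the small junction resections NHEJ produces).
#' @param force if `TRUE`, a re-cleavable `replacement_fwd` junction
#'   (which defeats the orientation-selection logic) downgrades from an
#'   error to a warning.
#' @return an object of class `design_report`: list with `recleavable`
#'   (named list of per-junction logical vectors for every non-original
#'   class), `n_guides_required`, `buffer_ok`, and `warnings`.
#' @export
validate_design <- function(design, min_buffer = 30L, force = FALSE) {
  outcomes <- enumerate_outcomes(design)
  guides <- unique(c(design$guide_left$protospacer,
                     design$guide_right$protospacer,
                     design$extra_guides))
  recleavable <- lapply(outcomes[setdiff(names(outcomes), "original")],
    function(a) {
      vapply(a$junctions$pos, junction_recleavable,
             logical(1), sequence = a$sequence, guides = guides)
    })
  warnings <- character()

  if (any(recleavable$replacement_fwd)) {
    msg <- "replacement_fwd junction(s) remain re-cleavable: correct products would be destroyed"
    if (!force) stop(msg, call. = FALSE)
    warnings <- c(warnings, msg)
  }
  if (!any(recleavable$deletion))
    warnings <- c(warnings,
      "deletion junction is not re-cleavable; add a gRNA targeting the deletion product to recycle it")
  if (!all(recleavable$replacement_rev))
    warnings <- c(warnings,
      "replacement_rev junction(s) not re-cleavable: no orientation selection against inverted donors")
  buffer_ok <- design$buffer_left >= min_buffer && design$buffer_right >= min_buffer
  if (design$buffer_left < min_buffer)
    warnings <- c(warnings, sprintf("left donor buffer %d nt is below the recommended %d nt",
                                    design$buffer_left, min_buffer))
  if (design$buffer_right < min_buffer)
    warnings <- c(warnings, sprintf("right donor buffer %d nt is below the recommended %d nt",
                                    design$buffer_right, min_buffer))
  n_guides <- length(guides)
  if (n_guides < 2 && !any(recleavable$deletion))
    warnings <- c(warnings, "a directional design requires at least two gRNAs")

  structure(list(recleavable = recleavable,
                 n_guides_required = max(2L, n_guides),
                 n_guides_supplied = n_guides,
                 buffer_ok = buffer_ok,
                 warnings = warnings),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Replace design report\n")
  cat(sprintf("  guides supplied: %d (minimum required: %d)\n",
              x$n_guides_supplied, x$n_guides_required))
  cat(sprintf("  sacrificial buffers ok: %s\n", x$buffer_ok))
  for (k in names(x$recleavable)) {
    cat(sprintf("  %-20s re-cleavable junctions: %s\n", k,
                paste(x$recleavable[[k]], collapse = ", ")))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  } else cat("  no warnings\n")
  invisible(x)
}

#' @exportS3Method base::format
format.design_report <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}

# design_report -> plain list for JSON serialization
#' @exportS3Method base::as.list
as.list.design_report <- function(x, ...) {
  list(recleavable = x$recleavable,
       n_guides_required = x$n_guides_required,
       n_guides_supplied = x$n_guides_supplied,
       buffer_ok = x$buffer_ok, warnings = x$warnings)
}

#' Generate a paper-style directional example design
#'
#' Builds a reporter-style locus in which one guide targets two identical
#' sites (both on the plus strand) flanking the segment to be replaced, and
#' a donor whose ends are the reverse-complemented break remnants of the
#' same guide. In this geometry the deletion and inverted-donor junctions
#' reform the full target site (re-cut and recycled), correct integration
#' disrupts it, and the downstream replacement junction ligates two
#' PAM-proximal ends -- the configuration in which staggered-cut fill-in
#' produces templated +1/+2 insertions.
#'
#' @param seed integer seed; the design is deterministic given the seed.
#' @param up,mid,down nt of sequence upstream of the left site, between the
#'   sites, and downstream of the right site.
#' @param buffer_left,buffer_right sacrificial buffer sizes inside the donor.
#' @param payload nt of donor payload between the buffers.
#' @return a [replace_design()].
#' @export
example_design <- function(seed = 1L, up = 260L, mid = 160L, down = 260L,
                           buffer_left = 30L, buffer_right = 30L,
                           payload = 60L) {
  with_seed(seed, {
    repeat {
      proto <- random_dna(20L)
      pam <- paste0(sample(DNA_BASES, 1), "GG")
      site <- paste0(proto, pam)
      locus <- paste0(random_dna(up), site, random_dna(mid), site, random_dna(down))
      donor <- paste0(revcomp(substr(proto, 1, 17)),
                      random_dna(buffer_left), random_dna(payload),
                      random_dna(buffer_right),
                      revcomp(paste0(substr(proto, 18, 20), pam)))
      sites <- locate_guide(locus, proto)
      if (length(sites) != 2L) next
      gL <- sites[[1]]; gR <- sites[[2]]
      des <- try(replace_design(
        locus, gL, gR, donor,
        donor_left_side = SIDE_PROTO, donor_right_side = SIDE_PAM,
        donor_left_guide = list(protospacer = proto, strand = "-"),
        donor_right_guide = list(protospacer = proto, strand = "-"),
        buffer_left = buffer_left, buffer_right = buffer_right),
        silent = TRUE)
      if (inherits(des, "try-error")) next
      rep_ok <- try(validate_design(des, min_buffer = min(buffer_left, buffer_right)),
                    silent = TRUE)
      if (inherits(rep_ok, "try-error")) next  # fwd junction coincidentally cleavable
      return(des)
    }
  })
}
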