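#' Default alignment scoring parameters
#'
#' Affine-gap scoring used throughout the package: match +2, mismatch -4,
#' gap of length L costs `gap_opening + gap_extension * L`.
#'
#' @param match,mismatch substitution scores.
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @param type `"global"` (Needleman-Wunsch) or `"global-local"`
#'   (query global, reference end-gaps free: the semi-global mode used when
#'   a read covers only part of a reference).
#' @return list of scoring parameters.
#' @export
align_params <- function(match = 2, mismatch = -4, gap_opening = 6,
                         gap_extension = 1, type = "global") {
  stopifnot(type %in% c("global", "global-local"))
  list(match = match, mismatch = mismatch, gap_opening = gap_opening,
       gap_extension = gap_extension, type = type)
}

subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = FALSE)
}

# run-length op table from two gapped alignment strings.
# Ops follow the read's perspective: 'deletion' = reference bases absent
# from the query; 'insertion' = query bases absent from the reference.
ops_from_gapped <- function(gp, gs, ref_offset = 0L) {
  p <- strsplit(gp, "")[[1]]
  s <- strsplit(gs, "")[[1]]
  cls <- ifelse(p == "-", "deletion",
         ifelse(s == "-", "insertion",
         ifelse(p == s, "match", "mismatch")))
  r <- rle(cls)
  n <- length(r$lengths)
  ref_consumed <- ifelse(r$values == "insertion", 0L, r$lengths)
  qry_consumed <- ifelse(r$values == "deletion", 0L, r$lengths)
  ref_start <- ref_offset + c(0L, cumsum(ref_consumed))[seq_len(n)]
  qry_start <- c(0L, cumsum(qry_consumed))[seq_len(n)]
  data.frame(op = r$values, length = r$lengths,
             ref_start = as.integer(ref_start),
             query_start = as.integer(qry_start),
             stringsAsFactors = FALSE)
}

pair_alignment <- function(ops, score, ref_start, ref_end, query, reference_id = NA_character_,
                           query_id = NA_character_) {
  structure(list(query_id = query_id, reference_id = reference_id,
                 ops = ops, score = score,
                 ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
                 query = query),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cig <- paste0(x$ops$length, substr(x$ops$op, 1, 1), collapse = "")
  cat(sprintf("pair_alignment score %.1f ref [%d,%d) %s\n",
              x$score, x$ref_start, x$ref_end, cig))
  invisible(x)
}

#' Optimal pairwise alignment of a read against a reference
#'
#' Affine-gap alignment via [Biostrings::pairwiseAlignment()], returned as
#' an ordered run-length operation table (match / mismatch / insertion /
#' deletion, read perspective) with 0-based half-open reference
#' coordinates. `type = "global-local"` leaves reference end-gaps free so a
#' read covering only part of a reference is not penalized for the
#' uncovered remainder.
#'
#' @param query,reference DNA strings.
#' @param params scoring from [align_params()].
#' @return a `pair_alignment` object: `ops` data.frame (`op`, `length`,
#'   `ref_start`, `query_start`), `score`, `ref_start`, `ref_end`.
#' @export
align_pair <- function(query, reference, params = align_params()) {
  assert_dna(query, "query"); assert_dna(reference, "reference")
  aln <- Biostrings::pairwiseAlignment(query, reference,
                                       substitutionMatrix = subst_matrix(params),
                                       gapOpening = params$gap_opening,
                                       gapExtension = params$gap_extension,
                                       type = params$type)
  ref_off <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  ops <- ops_from_gapped(as.character(Biostrings::alignedPattern(aln)),
                         as.character(Biostrings::alignedSubject(aln)),
                         ref_offset = ref_off)
  pair_alignment(ops, BiocGenerics::score(aln), ref_off,
                 BiocGenerics::end(Biostrings::subject(aln)), query)
}

# alignment summary without operation extraction (score, reference span,
# match count) -- much cheaper than align_pair when ops are not needed
align_summary <- function(query, reference, params = align_params()) {
  aln <- Biostrings::pairwiseAlignment(query, reference,
                                       substitutionMatrix = subst_matrix(params),
                                       gapOpening = params$gap_opening,
                                       gapExtension = params$gap_extension,
                                       type = params$type)
  list(score = BiocGenerics::score(aln),
       ref_start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
       ref_end = BiocGenerics::end(Biostrings::subject(aln)),
       nmatch = Biostrings::nmatch(aln))
}

# vectorized score-only alignment of many queries against one reference
alignment_scores <- function(queries, reference, params = align_params()) {
  if (length(queries) == 0) return(numeric(0))
  Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(queries), reference,
                                substitutionMatrix = subst_matrix(params),
                                gapOpening = params$gap_opening,
                                gapExtension = params$gap_extension,
                                type = params$type, scoreOnly = TRUE)
}

# batched full alignments of many queries against one reference;
# returns a list of pair_alignment
align_batch <- function(queries, reference, params = align_params(),
                        reference_id = NA_character_) {
  if (length(queries) == 0) return(list())
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(queries), reference,
                                       substitutionMatrix = subst_matrix(params),
                                       gapOpening = params$gap_opening,
                                       gapExtension = params$gap_extension,
                                       type = params$type)
  gp <- as.character(Biostrings::alignedPattern(aln))
  gs <- as.character(Biostrings::alignedSubject(aln))
  offs <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  ends <- BiocGenerics::end(Biostrings::subject(aln))
  scores <- BiocGenerics::score(aln)
  lapply(seq_along(queries), function(i) {
    pair_alignment(ops_from_gapped(gp[i], gs[i], offs[i]), scores[i],
                   offs[i], ends[i], queries[i], reference_id = reference_id)
  })
}
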