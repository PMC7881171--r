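#' Read a FASTA file
#'
#' @param path path to a (multi-)FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Read ids may carry key=value tags (e.g. `umi=ACGTACGTAC`) after the first
#' whitespace; these are parsed into columns.
#'
#' @param path path to an uncompressed 4-line-record FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `qualities`, and `umi`
#'   (NA where absent).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  # read as raw strings first so malformed bases are reported with the
  # read id instead of a parser error
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  seqs <- as.character(x)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTQ contains non-ACGTN bases in read: ",
         sub("\\s.*", "", names(x)[which(bad)[1]]), call. = FALSE)
  }
  full_id <- names(x)
  id <- sub("\\s.*", "", full_id)
  umi <- rep(NA_character_, length(id))
  has_umi <- grepl("umi=([ACGTN]+)", full_id)
  umi[has_umi] <- sub(".*umi=([ACGTN]+).*", "\\1", full_id[has_umi])
  data.frame(id = id, sequence = seqs,
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             umi = umi, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table as FASTQ
#'
#' UMIs, when present, are appended to the header as `umi=<seq>`.
#'
#' @param reads data.frame with `id`, `sequence`, and optionally `qualities`
#'   and `umi` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  hdr <- reads$id
  if (!is.null(reads$umi)) {
    has <- !is.na(reads$umi)
    hdr[has] <- paste0(hdr[has], " umi=", reads$umi[has])
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- hdr
  qual <- if (is.null(reads$qualities)) {
    strrep("I", nchar(reads$sequence))
  } else reads$qualities
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a BED file of predicted sites
#'
#' BED is 0-based half-open; at least 3 columns are required. Parsing is
#' delegated to [rtracklayer::import.bed()] after a light structural check
#' that reports offending line numbers.
#'
#' @param path path to a BED file.
#' @return a [GenomicRanges::GRanges] object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3) stop("BED line ", i, ": fewer than 3 columns", call. = FALSE)
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("BED line ", i, ": non-numeric interval", call. = FALSE)
    if (e <= s) stop("BED line ", i, ": end <= start", call. = FALSE)
  }
  rtracklayer::import(path, format = "BED")
}

#' Write genomic positions as BED
#'
#' @param gr a [GenomicRanges::GRanges] object.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a guide TSV (name, 20-nt protospacer)
#'
#' @param path two-column tab-separated file without header.
#' @return data.frame with columns `name` and `protospacer`.
#' @export
read_guides_tsv <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("name", "protospacer"),
                         colClasses = "character")
  for (i in seq_len(nrow(g))) {
    if (nchar(g$protospacer[i]) != 20 || grepl("[^ACGT]", g$protospacer[i]))
      stop("guide TSV line ", i, ": protospacer must be a 20-nt ACGT string",
           call. = FALSE)
  }
  g
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write an R list as JSON
#' @param x list.
#' @param path output path.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an outcome-mixture YAML config
#'
#' Recognised keys are the arguments of [outcome_mixture()]; `weights` is a
#' named map over outcome classes.
#'
#' @param path YAML file path.
#' @return an `outcome_mixture` object.
#' @export
read_mixture_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$weights)) cfg$weights <- unlist(cfg$weights)
  do.call(outcome_mixture, cfg)
}
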