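#' Construct a set of sequence records
#'
#' The common currency of the pipeline: one row per read, with the read id,
#' its uppercase nucleotide sequence and sample/region labels.
#'
#' @param id character vector of unique read identifiers.
#' @param seq character vector of nucleotide sequences (IUPAC alphabet).
#' @param sample sample label, recycled.
#' @param region amplicon region label: `"V1V2"`, `"V6"` or `"unknown"`.
#' @return a `data.frame` with columns `id`, `seq`, `sample`, `region`.
#' @export
sequence_records <- function(id, seq, sample = "unknown", region = "unknown") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    stop("duplicate sequence id: '", dup, "'")
  }
  if (length(seq) > 0 && any(!nzchar(seq))) stop("empty sequence not allowed")
  bad <- grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"), seq)
  if (any(bad))
    stop("non-IUPAC characters in sequence for id '", id[bad][1], "'")
  vapply(region, check_region, character(1))
  data.frame(id = id, seq = seq,
             sample = rep_len(as.character(sample), length(id)),
             region = rep_len(as.character(region), length(id)),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into sequence records
#'
#' Sequences are uppercased and whitespace-stripped; entry order is
#' preserved. Ids (first whitespace-delimited token of the header) must be
#' unique within a file. Structural problems are reported with the
#' offending 1-based line number.
#'
#' @param path path to a FASTA file.
#' @param sample,region labels attached to every record.
#' @return a sequence-record `data.frame` (see [sequence_records()]).
#' @export
read_fasta <- function(path, sample = "unknown", region = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(sequence_records(character(0), character(0), sample, region))
  }
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[nonblank[1]])
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  hdr <- which(is_header)
  # every header must be followed by at least one sequence line
  for (h in hdr) {
    nxt <- nonblank[nonblank > h]
    if (length(nxt) == 0 || is_header[nxt[1]])
      stop("malformed FASTA: empty sequence for header at line ", h)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: '", ids[duplicated(ids)][1], "'")
  seqs <- gsub("\\s", "", toupper(as.character(set)))
  sequence_records(ids, seqs, sample = sample, region = region)
}

#' Write sequence records to a FASTA file
#'
#' @param records a sequence-record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
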