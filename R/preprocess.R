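#' Construct a dereplicated set
#'
#' Unique sequences with read counts; the read counts are the abundance
#' weights used by every downstream stage.
#'
#' @param id representative ids (first-occurrence read ids).
#' @param seq distinct sequences.
#' @param count reads per sequence.
#' @param members list of member read-id vectors, one per entry.
#' @param region amplicon region label.
#' @return a `derep_set` list.
#' @export
derep_set <- function(id, seq, count, members = NULL, region = "unknown") {
  if (anyDuplicated(seq)) stop("derep sequences must be pairwise distinct")
  if (length(count) > 0 && any(count < 1)) stop("derep counts must be >= 1")
  if (is.null(members)) members <- as.list(id)
  if (length(members) != length(id)) stop("members length must match entries")
  got <- vapply(members, length, integer(1))
  if (length(got) > 0 && any(got != count))
    stop("member list lengths must equal counts")
  structure(list(id = as.character(id), seq = as.character(seq),
                 count = as.integer(count), members = members,
                 region = check_region(region)),
            class = "derep_set")
}

#' @export
print.derep_set <- function(x, ...) {
  cat("derep_set:", length(x$id), "unique sequences,",
      sum(x$count), "reads, region", x$region, "\n")
  invisible(x)
}

#' Total reads behind a dereplicated set
#' @param dereps a `derep_set`.
#' @return integer read count.
#' @export
derep_reads <- function(dereps) sum(dereps$count)

#' Split reads into amplicon regions by exact primer match
#'
#' A read is assigned to a region iff its 5' end matches that region's
#' forward composite primer (adapter + target) exactly; IUPAC ambiguity
#' codes in the primer match their base sets, never the reverse. Reads
#' matching no primer are discarded (and counted); a read matching two
#' regions' primers is a configuration error.
#'
#' @param reads sequence records.
#' @param primers a [primer_table()]; only forward-orientation rows are
#'   used for splitting.
#' @return a list with one sequence-record `data.frame` per region plus
#'   attribute `discarded` (number of unassigned reads).
#' @export
split_by_primer <- function(reads, primers) {
  fwd <- primers[primers$orientation == "forward", , drop = FALSE]
  if (nrow(fwd) == 0) stop("no forward primers supplied")
  hit <- matrix(FALSE, nrow(reads), nrow(fwd))
  for (k in seq_len(nrow(fwd))) {
    pat <- paste0("^", iupac_regex(fwd$composite[k]))
    hit[, k] <- grepl(pat, reads$seq)
  }
  nhits <- rowSums(hit)
  if (any(nhits > 1)) {
    bad <- reads$id[which(nhits > 1)[1]]
    stop("primers are not prefix-disjoint: read '", bad,
         "' matches more than one region")
  }
  out <- list()
  for (k in seq_len(nrow(fwd))) {
    reg <- fwd$region[k]
    sel <- reads[hit[, k], , drop = FALSE]
    sel$region <- rep(reg, nrow(sel))
    rownames(sel) <- NULL
    out[[reg]] <- sel
  }
  attr(out, "discarded") <- sum(nhits == 0)
  out
}

#' Trim the forward primer and apply the minimum length cutoff
#'
#' Removes the adapter+target prefix and drops reads whose trimmed length
#' falls below the region's minimum; the cutoff is inclusive (length >=
#' cutoff is kept). Defaults are 218 nt for V1V2 and 235 nt for V6.
#'
#' @param reads region-assigned sequence records.
#' @param primer the forward primer row for this region.
#' @param min_len minimum trimmed read length; `NULL` uses the region
#'   default.
#' @return trimmed sequence records.
#' @export
trim_and_filter <- function(reads, primer, min_len = NULL) {
  if (is.null(min_len)) min_len <- region_min_len(primer$region)
  plen <- nchar(primer$adapter) + nchar(primer$target)
  trimmed <- substr(reads$seq, plen + 1L, nchar(reads$seq))
  keep <- nchar(trimmed) >= min_len
  out <- reads[keep, , drop = FALSE]
  out$seq <- trimmed[keep]
  rownames(out) <- NULL
  out
}

#' Region default minimum trimmed-read lengths
#' @param region `"V1V2"` or `"V6"`.
#' @return integer length cutoff.
#' @export
region_min_len <- function(region) {
  switch(check_region(region), V1V2 = 218L, V6 = 235L,
         stop("no default length cutoff for region '", region, "'"))
}

#' Collapse reads to unique sequences
#'
#' Identical sequences are merged; the representative id is the id of the
#' first occurrence and read counts are conserved.
#'
#' @param reads sequence records.
#' @return a [derep_set()], in first-occurrence order.
#' @export
dereplicate <- function(reads) {
  region <- if (nrow(reads) > 0) reads$region[1] else "unknown"
  if (nrow(reads) == 0)
    return(derep_set(character(0), character(0), integer(0),
                     region = region))
  first <- !duplicated(reads$seq)
  key <- match(reads$seq, reads$seq[first])
  members <- split(reads$id, key)
  members <- members[order(as.integer(names(members)))]
  derep_set(id = reads$id[first], seq = reads$seq[first],
            count = as.integer(tabulate(key, nbins = sum(first))),
            members = unname(members), region = region)
}

# Alignment difference count between two sequences: mismatches plus
# internal gap columns. With hp_discount, an internal indel column whose
# base extends a homopolymer run of length >= 2 in the ungapped sequence
# counts half a difference.
#' @noRd
count_diffs <- function(a, b, hp_discount = FALSE,
                        match = 1, mismatch = -1, gap = -2) {
  if (!hp_discount) return(nw_diffs_cpp(a, b, match, mismatch, gap))
  # canonical order, mirroring the distance helpers
  if (nchar(b) < nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  aln <- nw_align_cpp(a, b, match, mismatch, gap)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  L <- length(ca)
  gapcol <- ca == "-" | cb == "-"
  # terminal runs of same-sequence gaps are end gaps
  endgap <- rep(FALSE, L)
  if (L > 0 && gapcol[1]) {
    which1 <- if (ca[1] == "-") ca else cb
    k <- 1
    while (k <= L && which1[k] == "-") { endgap[k] <- TRUE; k <- k + 1 }
  }
  if (L > 0 && gapcol[L] && !endgap[L]) {
    whichL <- if (ca[L] == "-") ca else cb
    k <- L
    while (k >= 1 && whichL[k] == "-" && !endgap[k]) {
      endgap[k] <- TRUE; k <- k - 1
    }
  }
  diffs <- 0
  for (k in which(!endgap)) {
    if (!gapcol[k]) {
      if (ca[k] != cb[k]) diffs <- diffs + 1
    } else {
      host <- if (ca[k] == "-") cb else ca  # sequence holding the base
      x <- host[k]
      run <- (k > 1 && host[k - 1] == x) || (k < L && host[k + 1] == x)
      diffs <- diffs + if (run) 0.5 else 1
    }
  }
  diffs
}

# Greedy abundance-ranked merger shared by denoise() and precluster():
# entries sorted (count desc, length desc, sequence lexicographic); each
# entry is absorbed by the first earlier retained seed within max_diffs
# differences of the seed's sequence. Counts and members accumulate.
#' @noRd
merge_by_diffs <- function(dereps, max_diffs, hp_discount = FALSE) {
  n <- length(dereps$id)
  if (n <= 1) return(dereps)
  ord <- lex_order(-dereps$count, -nchar(dereps$seq), dereps$seq)
  id <- dereps$id[ord]; seq <- dereps$seq[ord]
  count <- dereps$count[ord]; members <- dereps$members[ord]
  keep_seq <- character(0); keep_idx <- integer(0)
  absorbed_into <- integer(0)
  for (e in seq_len(n)) {
    target <- 0L
    for (s in seq_along(keep_idx)) {
      if (count_diffs(seq[e], keep_seq[s], hp_discount) <= max_diffs) {
        target <- s; break
      }
    }
    if (target == 0L) {
      keep_idx <- c(keep_idx, e)
      keep_seq <- c(keep_seq, seq[e])
      absorbed_into <- c(absorbed_into, length(keep_idx))
    } else {
      absorbed_into <- c(absorbed_into, target)
    }
  }
  out_count <- integer(length(keep_idx))
  out_members <- vector("list", length(keep_idx))
  for (e in seq_len(n)) {
    t <- absorbed_into[e]
    out_count[t] <- out_count[t] + count[e]
    out_members[[t]] <- c(out_members[[t]], members[[e]])
  }
  res <- derep_set(id = id[keep_idx], seq = seq[keep_idx],
                   count = out_count, members = out_members,
                   region = dereps$region)
  # re-sort so the output ordering invariant holds after accumulation
  ord2 <- lex_order(-res$count, -nchar(res$seq), res$seq)
  derep_set(res$id[ord2], res$seq[ord2], res$count[ord2],
            res$members[ord2], res$region)
}

#' Abundance-ranked sequence-space denoiser
#'
#' Greedy merger absorbing low-abundance entries into more abundant ones
#' within `max_diffs` alignment differences, a sequence-space treatment of
#' the homopolymer-indel error structure of pyrosequencing reads. With
#' `hp_discount` an indel adjacent to a homopolymer run of length >= 2
#' counts half a difference, so the platform's characteristic errors are
#' absorbed at a wider effective radius than substitutions.
#'
#' @param dereps a [derep_set()].
#' @param max_diffs merge radius in (possibly discounted) differences.
#' @param hp_discount halve the cost of homopolymer-adjacent indels?
#' @return a denoised `derep_set` sorted by (count desc, length desc,
#'   sequence).
#' @export
denoise <- function(dereps, max_diffs = 3, hp_discount = TRUE) {
  if (max_diffs < 0) stop("max_diffs must be >= 0")
  merge_by_diffs(dereps, max_diffs, hp_discount)
}

#' Per-stage read counters
#'
#' @param total_reads,after_split,after_length_cutoff,after_denoise,after_decontam
#'   read counts at the successive stages; must be non-increasing.
#' @return a `pipeline_counters` list.
#' @export
pipeline_counters <- function(total_reads, after_split, after_length_cutoff,
                              after_denoise, after_decontam) {
  v <- c(total_reads, after_split, after_length_cutoff, after_denoise,
         after_decontam)
  if (any(v < 0)) stop("counters must be non-negative")
  if (any(diff(v) > 0)) stop("counters must be non-increasing")
  structure(as.list(setNames(v, c("total_reads", "after_split",
                                  "after_length_cutoff", "after_denoise",
                                  "after_decontam"))),
            class = "pipeline_counters")
}
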