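#' Global alignment of two sequences with free terminal gaps
#'
#' Optimal Needleman-Wunsch alignment under per-column scoring with
#' terminal gap runs free (semi-global). Traceback is deterministic:
#' diagonal is preferred over a gap in `b`, which is preferred over a gap
#' in `a`. Column accounting follows the package's distance convention:
#' terminal gap runs are end gaps and are discounted; every internal gap
#' column counts as a difference of its own.
#'
#' @param a,b nucleotide sequences (non-empty).
#' @param match,mismatch,gap per-column scores.
#' @return a list with `aligned_a`, `aligned_b`, `score`, `mismatches`,
#'   `internal_gap_cols`, `endgap_cols`, `compared_cols`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap)
}

#' Pairwise alignment distance
#'
#' `(mismatches + internal gap columns) / compared columns` of the optimal
#' free-end-gap alignment, where compared columns exclude terminal gap
#' runs; defined as 0 when no columns are compared.
#'
#' @inheritParams align_pair
#' @return a distance in [0, 1].
#' @export
seq_distance <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  nw_dist_cpp(toupper(a), toupper(b), match, mismatch, gap)
}

#' Pairwise distance matrix of a dereplicated set
#'
#' All unordered pairs are aligned once and mirrored.
#'
#' @param seqs a [derep_set()], or a named character vector of sequences.
#' @param match,mismatch,gap per-column alignment scores.
#' @return a symmetric matrix with zero diagonal, ids as `dimnames`.
#' @export
pairwise_distance_matrix <- function(seqs, match = 1, mismatch = -1,
                                     gap = -2) {
  if (inherits(seqs, "derep_set")) {
    ids <- seqs$id
    ss <- seqs$seq
  } else {
    ss <- as.character(seqs)
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("s%d", seq_along(ss))
  }
  if (length(ss) < 1) stop("need at least one sequence")
  d <- pairwise_dist_cpp(toupper(ss), match, mismatch, gap)
  dimnames(d) <- list(ids, ids)
  d
}
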