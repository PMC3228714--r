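#' Pool sample and control sequences with equal-representation weights
#'
#' Control entries are weighted so that the weighted control total equals
#' the sample read total exactly: sample entries carry weight = read
#' count, control entries carry weight = read count x (sample reads /
#' control reads). This is the equal-representation contract that makes
#' the majority rule of [filter_contaminants()] meaningful for any read
#' depth ratio.
#'
#' @param sample a [derep_set()] of the sample.
#' @param control a [derep_set()] of its negative extraction control.
#' @return a `labeled_pool` data.frame with columns `pool_id`, `id`,
#'   `seq`, `count`, `source`, `weight`.
#' @export
weight_controls <- function(sample, control) {
  ns <- derep_reads(sample)
  nc <- derep_reads(control)
  if (ns < 1) stop("sample has no reads")
  if (nc < 1) stop("control has no reads")
  mult <- ns / nc
  pool <- data.frame(
    pool_id = c(paste0("S:", sample$id), paste0("C:", control$id)),
    id = c(sample$id, control$id),
    seq = c(sample$seq, control$seq),
    count = c(sample$count, control$count),
    source = rep(c("sample", "control"),
                 c(length(sample$id), length(control$id))),
    weight = c(as.numeric(sample$count), control$count * mult),
    stringsAsFactors = FALSE)
  attr(pool, "control_multiplier") <- mult
  attr(pool, "region") <- sample$region
  attr(pool, "members_sample") <- c(sample$members, control$members)
  class(pool) <- c("labeled_pool", "data.frame")
  pool
}

#' Remove sample sequences that cluster with the negative control
#'
#' Complete-linkage clustering of the pooled sample + control sequences at
#' `cutoff` genetic difference; within each cluster the control share is
#' computed (on equal-representation weights by default) and every sample
#' entry in a cluster whose control share reaches `threshold` (boundary
#' inclusive: "50% or more") is removed.
#'
#' @param pool a `labeled_pool` from [weight_controls()].
#' @param cutoff clustering cutoff (default 0.01, i.e. 1% difference).
#' @param threshold control share at or above which sample members are
#'   removed (default 0.5).
#' @param count_mode `"weights"` (default) computes the control share on
#'   pool weights; `"entries"` counts unique entries instead.
#' @return `list(kept = derep_set of retained sample entries, report =
#'   data.frame of removed ids with their cluster's control fraction)`.
#' @export
filter_contaminants <- function(pool, cutoff = 0.01, threshold = 0.5,
                                count_mode = c("weights", "entries")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(pool, "labeled_pool"))
  d <- pairwise_distance_matrix(setNames(pool$seq, pool$pool_id))
  part <- hier_cluster(d, counts = pool$count, linkage = "complete",
                       cutoffs = cutoff)[[1]]
  cl <- part$assignment[pool$pool_id]
  wt <- if (count_mode == "weights") pool$weight else rep(1, nrow(pool))
  ctl <- tapply(wt * (pool$source == "control"), cl, sum)
  tot <- tapply(wt, cl, sum)
  fr <- ctl / tot
  frac <- as.numeric(fr[as.character(cl)])
  removed <- pool$source == "sample" & frac >= threshold
  keep <- pool$source == "sample" & !removed
  report <- data.frame(id = pool$id[removed],
                       cluster = as.integer(cl[removed]),
                       control_fraction = frac[removed],
                       stringsAsFactors = FALSE)
  kept_idx <- which(keep)
  list(kept = list_to_derep(pool, kept_idx), report = report)
}

#' @noRd
list_to_derep <- function(pool, idx) {
  derep_set(id = pool$id[idx], seq = pool$seq[idx],
            count = pool$count[idx],
            members = attr(pool, "members_sample")[idx],
            region = attr(pool, "region") %||% "unknown")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decontaminate a sample against its negative extraction control
#'
#' Convenience wrapper: weights the control for equal representation,
#' clusters the pooled sequences at `cutoff` by complete linkage, and
#' removes sample sequences in majority-control clusters. With an empty
#' (or absent) control the filter is skipped with a warning and the
#' sample is returned unchanged.
#'
#' @param sample a [derep_set()] of the sample.
#' @param control a [derep_set()] of the control, or `NULL`.
#' @inheritParams filter_contaminants
#' @return `list(kept, report, skipped)`.
#' @export
decontaminate <- function(sample, control, cutoff = 0.01, threshold = 0.5,
                          count_mode = c("weights", "entries")) {
  if (is.null(control) || derep_reads(control) == 0) {
    warning("empty negative control: contamination filter skipped")
    return(list(kept = sample,
                report = data.frame(id = character(0), cluster = integer(0),
                                    control_fraction = numeric(0)),
                skipped = TRUE))
  }
  pool <- weight_controls(sample, control)
  res <- filter_contaminants(pool, cutoff, threshold, count_mode)
  list(kept = res$kept, report = res$report, skipped = FALSE)
}
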