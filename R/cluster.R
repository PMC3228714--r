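#' Abundance-ranked preclustering
#'
#' Single pass over entries sorted by (count desc, length desc, sequence):
#' each entry merges into the first earlier retained seed within
#' `max_diffs` alignment differences of the seed's sequence (differences =
#' mismatches + internal gap columns). Absorbs residual sequencing noise
#' before OTU formation.
#'
#' @param dereps a [derep_set()].
#' @param max_diffs maximum differing nucleotides for a merge (default 2).
#' @return a preclustered `derep_set`.
#' @export
precluster <- function(dereps, max_diffs = 2) {
  if (max_diffs < 0) stop("max_diffs must be >= 0")
  merge_by_diffs(dereps, max_diffs, hp_discount = FALSE)
}

#' Number of unique sequences (cutoff-0 OTUs)
#'
#' @param dereps a [derep_set()].
#' @return integer count of distinct sequences.
#' @export
unique_otus <- function(dereps) length(dereps$id)

#' Hierarchical OTU clustering at one or more cutoffs
#'
#' Agglomerative clustering over a pairwise distance matrix. The merge
#' criterion is the minimum (single), maximum (complete) or read-count
#' weighted mean (average) of inter-cluster distances. A partition is
#' emitted at each requested cutoff: it contains every merge whose
#' criterion is at most the cutoff, and merging toward that partition
#' stops at the first merge whose criterion exceeds it. Ties in merge
#' order are broken by the lowest pair of smallest member indices, making
#' runs deterministic.
#'
#' @param d symmetric distance matrix with ids as `dimnames`.
#' @param counts read counts per sequence, in matrix order (also the
#'   abundance weights for average linkage when `weighted = TRUE`).
#' @param linkage `"single"`, `"average"` or `"complete"`.
#' @param cutoffs numeric cutoffs in (0, 1).
#' @param weighted weight average linkage by read counts? If `FALSE`
#'   every unique sequence carries weight 1.
#' @return a named list of `otu_partition` objects, one per cutoff.
#' @export
hier_cluster <- function(d, counts, linkage = c("average", "single",
                                                "complete"),
                         cutoffs, weighted = TRUE) {
  linkage <- match.arg(linkage)
  validate_dist_matrix(d)
  if (any(cutoffs <= 0 | cutoffs >= 1)) stop("cutoffs must lie in (0, 1)")
  n <- nrow(d)
  ids <- rownames(d)
  counts <- as.integer(counts)
  if (length(counts) != n) stop("counts length must match matrix")
  w <- if (weighted) as.numeric(counts) else rep(1, n)

  cutoffs_sorted <- sort(unique(cutoffs))
  pending <- cutoffs_sorted
  partitions <- list()
  members <- as.list(seq_len(n))
  minmem <- seq_len(n)
  active <- rep(TRUE, n)
  clw <- w
  C <- d
  diag(C) <- Inf

  emit <- function(cut) {
    make_partition(cut, linkage, ids, counts, members[active])
  }

  while (sum(active) > 1) {
    Cm <- C
    Cm[!active, ] <- Inf
    Cm[, !active] <- Inf
    v <- min(Cm)
    cand <- which(Cm == v, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(minmem[cand[, 1]], minmem[cand[, 2]])
    key2 <- pmax(minmem[cand[, 1]], minmem[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (minmem[j] < minmem[i]) { tmp <- i; i <- j; j <- tmp }

    while (length(pending) > 0 && v > pending[1]) {
      partitions[[format_cutoff(pending[1])]] <- emit(pending[1])
      pending <- pending[-1]
    }

    ks <- which(active & seq_len(n) != i & seq_len(n) != j)
    newc <- switch(linkage,
      single = pmin(C[i, ks], C[j, ks]),
      complete = pmax(C[i, ks], C[j, ks]),
      average = (clw[i] * C[i, ks] + clw[j] * C[j, ks]) / (clw[i] + clw[j]))
    C[i, ks] <- newc
    C[ks, i] <- newc
    members[[i]] <- c(members[[i]], members[[j]])
    minmem[i] <- min(minmem[i], minmem[j])
    clw[i] <- clw[i] + clw[j]
    active[j] <- FALSE
  }
  for (cut in pending) partitions[[format_cutoff(cut)]] <- emit(cut)
  partitions
}

#' @noRd
format_cutoff <- function(cut) as.character(cut)

# Build an otu_partition from cluster member index vectors.
#' @noRd
make_partition <- function(cutoff, linkage, ids, counts, member_sets) {
  ord <- order(vapply(member_sets, min, integer(1)))
  member_sets <- member_sets[ord]
  assignment <- integer(length(ids))
  for (k in seq_along(member_sets)) assignment[member_sets[[k]]] <- k
  names(assignment) <- ids
  cluster_counts <- vapply(member_sets,
                           function(mm) sum(counts[mm]), numeric(1))
  structure(list(cutoff = cutoff, linkage = linkage,
                 assignment = assignment,
                 cluster_counts = as.integer(cluster_counts),
                 n_otus = length(member_sets)),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat("otu_partition:", x$n_otus, "OTUs at cutoff", x$cutoff,
      paste0("(", x$linkage, " linkage), "),
      sum(x$cluster_counts), "reads\n")
  invisible(x)
}

#' Write an OTU membership list
#'
#' Tab-separated rows: cutoff, cluster id, comma-separated member ids.
#'
#' @param partition an `otu_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_partition <- function(partition, path) {
  a <- partition$assignment
  lines <- vapply(seq_len(partition$n_otus), function(k) {
    paste(format_cutoff(partition$cutoff), sprintf("OTU%04d", k),
          paste(names(a)[a == k], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OTU membership list written by [write_otu_partition()]
#'
#' @param path input path.
#' @return an `otu_partition` (cluster read counts equal member counts of
#'   1 per sequence, since the file does not carry abundances).
#' @export
read_otu_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3)) stop("OTU list: expected 3 tab-separated fields")
  cutoff <- unique(vapply(f, `[[`, character(1), 1L))
  if (length(cutoff) != 1) stop("OTU list mixes cutoffs")
  member_sets <- strsplit(vapply(f, `[[`, character(1), 3L), ",", fixed = TRUE)
  ids <- unlist(member_sets)
  idx_sets <- lapply(member_sets, function(mm) match(mm, ids))
  make_partition(as.numeric(cutoff), "unknown", ids,
                 rep(1L, length(ids)), idx_sets)
}
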