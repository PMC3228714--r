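#' Replicate per-representative hits onto member reads
#'
#' Searches are run once per unique (dereplicated) sequence; to make
#' downstream assignment abundance-aware, each member read of a
#' dereplicated entry receives a copy of its representative's hit list.
#'
#' @param hits named list of hit `data.frame`s keyed by representative id
#'   (see [read_hit_table()]).
#' @param dereps the [derep_set()] the hits were computed from.
#' @return a named list of hit `data.frame`s keyed by read id.
#' @export
replicate_hits <- function(hits, dereps) {
  unknown <- setdiff(names(hits), dereps$id)
  if (length(unknown) > 0)
    stop("hit query '", unknown[1], "' is not a representative id")
  out <- list()
  for (k in seq_along(dereps$id)) {
    rep_id <- dereps$id[k]
    h <- hits[[rep_id]]
    if (is.null(h)) next
    for (read_id in dereps$members[[k]]) out[[read_id]] <- h
  }
  out
}

#' Lowest-common-ancestor taxonomic assignment
#'
#' Per read: hits below `min_score` bits are dropped; of the remainder,
#' hits within `top_percent` of the best score are retained
#' (`bit_score >= (1 - top_percent) * best`); the read is assigned to the
#' lowest common ancestor of the retained hit taxa. Reads with no
#' retained hits (or no hits at all) fall into the `"NoHits"` bucket.
#'
#' @param read_hits named list of per-read hit `data.frame`s (see
#'   [replicate_hits()]).
#' @param tree a `taxonomy_tree`.
#' @param min_score minimum alignment bit score (default 100).
#' @param top_percent score window below the best hit (default 0.10;
#'   use 1 to keep every hit above `min_score`).
#' @param read_ids all reads to assign; reads absent from `read_hits`
#'   are bucketed as `"NoHits"`.
#' @return an assignment `data.frame` with columns `read_id`, `node`.
#' @export
lca_assign <- function(read_hits, tree, min_score = 100, top_percent = 0.10,
                       read_ids = names(read_hits)) {
  unknown <- setdiff(unique(unlist(lapply(read_hits, `[[`, "subject_taxon"))),
                     tree$id)
  if (length(unknown) > 0)
    stop("hit names unknown taxon '", unknown[1], "'")
  lca_cache <- new.env(parent = emptyenv())
  node <- vapply(read_ids, function(rid) {
    h <- read_hits[[rid]]
    if (is.null(h) || nrow(h) == 0) return("NoHits")
    h <- h[h$bit_score >= min_score, , drop = FALSE]
    if (nrow(h) == 0) return("NoHits")
    best <- max(h$bit_score)
    taxa <- sort(unique(h$subject_taxon[h$bit_score >= (1 - top_percent) * best]))
    key <- paste(taxa, collapse = "\r")
    if (is.null(lca_cache[[key]])) lca_cache[[key]] <- tax_lca(tree, taxa)
    lca_cache[[key]]
  }, character(1))
  data.frame(read_id = read_ids, node = unname(node),
             stringsAsFactors = FALSE)
}

#' Minimum-support filter
#'
#' Taxa to which fewer than `min_support` reads are assigned are not
#' reported: their reads move to the `"NotAssigned"` bucket. Applied once
#' over the final per-node tallies; the boundary is inclusive (a node
#' with exactly `min_support` reads is reported).
#'
#' @param assignment an assignment `data.frame` from [lca_assign()].
#' @param min_support minimum reads per reported taxon (default 5).
#' @return the filtered assignment `data.frame`.
#' @export
apply_min_support <- function(assignment, min_support = 5L) {
  if (min_support < 1) stop("min_support must be >= 1")
  real <- !(assignment$node %in% c("NotAssigned", "NoHits"))
  tally <- table(assignment$node[real])
  weak <- names(tally)[tally < min_support]
  assignment$node[assignment$node %in% weak] <- "NotAssigned"
  assignment
}

# Ancestor of `node` at `rank`, or NA if the path has none.
#' @noRd
rank_ancestor <- function(tree, node, rank) {
  path <- tax_ancestry(tree, node)
  ranks <- tree$rank[match(path, tree$id)]
  hit <- path[ranks == rank]
  if (length(hit) == 1) hit else NA_character_
}

#' Normalize per-sample assignments and summarize by rank
#'
#' Each sample's node tallies are scaled to a common read total
#' (`target`, default 100000) so samples of unequal depth are
#' comparable; summaries are emitted at the phylum, order and genus
#' ranks (a node's tally at a rank is the scaled number of reads
#' assigned at or below it), together with the per-sample counts of
#' distinct phyla and genera.
#'
#' @param results named list of assignment `data.frame`s, one per sample.
#' @param tree the `taxonomy_tree` used for assignment.
#' @param target common read total to scale to.
#' @return a list with `tables` (named list of rank-by-sample matrices),
#'   `counts` (`data.frame` of distinct phyla/genera per sample) and
#'   `buckets` (per-sample assigned / NotAssigned / NoHits read counts).
#' @export
normalize_and_summarize <- function(results, tree, target = 100000) {
  if (target <= 0) stop("target must be > 0")
  samples <- names(results)
  nodes <- setdiff(unique(unlist(lapply(results, `[[`, "node"))),
                   c("NotAssigned", "NoHits"))
  anc <- list(
    phylum = vapply(nodes, function(nd) rank_ancestor(tree, nd, "phylum"),
                    character(1)),
    order = vapply(nodes, function(nd) rank_ancestor(tree, nd, "order"),
                   character(1)),
    genus = vapply(nodes, function(nd) rank_ancestor(tree, nd, "genus"),
                   character(1)))
  tables <- list()
  for (rank in names(anc)) {
    rnodes <- sort(unique(anc[[rank]][!is.na(anc[[rank]])]))
    tab <- matrix(0, length(rnodes), length(samples),
                  dimnames = list(rnodes, samples))
    tables[[rank]] <- tab
  }
  buckets <- data.frame(sample = samples, assigned = 0L,
                        not_assigned = 0L, no_hits = 0L,
                        stringsAsFactors = FALSE)
  for (s in seq_along(samples)) {
    a <- results[[samples[s]]]
    total <- nrow(a)
    scale <- if (total > 0) target / total else 0
    tally <- table(a$node)
    buckets$not_assigned[s] <- sum(a$node == "NotAssigned")
    buckets$no_hits[s] <- sum(a$node == "NoHits")
    buckets$assigned[s] <- total - buckets$not_assigned[s] -
      buckets$no_hits[s]
    for (rank in names(anc)) {
      for (nd in names(tally)) {
        if (nd %in% c("NotAssigned", "NoHits")) next
        up <- anc[[rank]][[nd]]
        if (!is.na(up))
          tables[[rank]][up, s] <- tables[[rank]][up, s] +
            tally[[nd]] * scale
      }
    }
  }
  counts <- data.frame(
    sample = samples,
    phyla = colSums(tables$phylum > 0),
    genera = colSums(tables$genus > 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(tables = tables, counts = counts, buckets = buckets)
}

#' Toy hit generator for synthetic data
#'
#' Scores each dereplicated sequence against every community template by
#' global alignment with a blastn-like bit score (+2 per match, -3 per
#' difference) so the taxonomy stage can be exercised without an external
#' search tool. Hits more than `max_dist` diverged from the query are not
#' reported.
#'
#' @param dereps a [derep_set()].
#' @param community a [community_model()] whose `taxa` maps template ids
#'   to taxonomy node ids.
#' @param top_k best hits kept per query (default 25).
#' @param max_dist maximum alignment distance for a reportable hit.
#' @return a named list of hit `data.frame`s keyed by representative id.
#' @export
toy_hit_table <- function(dereps, community, top_k = 25L, max_dist = 0.30) {
  if (is.null(community$taxa)) stop("community has no taxonomy mapping")
  out <- list()
  tnames <- names(community$templates)
  for (k in seq_along(dereps$id)) {
    q <- dereps$seq[k]
    stats <- lapply(community$templates, function(t) nw_align_cpp(q, t))
    dist <- vapply(stats, function(s) {
      if (s$compared_cols == 0) 0
      else (s$mismatches + s$internal_gap_cols) / s$compared_cols
    }, numeric(1))
    bits <- vapply(stats, function(s) {
      diffs <- s$mismatches + s$internal_gap_cols
      2 * (s$compared_cols - diffs) - 3 * diffs
    }, numeric(1))
    keep <- which(dist <= max_dist)
    if (length(keep) == 0) next
    keep <- keep[lex_order(-bits[keep], tnames[keep])]
    keep <- head(keep, top_k)
    out[[dereps$id[k]]] <- data.frame(
      subject_taxon = unname(community$taxa[tnames[keep]]),
      bit_score = unname(bits[keep]),
      evalue = rep(1e-30, length(keep)),
      stringsAsFactors = FALSE)
  }
  out
}
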