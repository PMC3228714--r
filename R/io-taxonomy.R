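TAX_RANKS <- c("root", "phylum", "order", "family", "genus", "species")

#' Build a taxonomy tree from ranked lineage strings
#'
#' Each reference taxon contributes a semicolon-delimited lineage
#' (phylum;order;family;genus;species, shorter lineages allowed). Shared
#' lineage prefixes share internal nodes. Internal nodes are keyed by
#' their name, the leaf by the supplied taxon id.
#'
#' @param ids character vector of leaf node ids (one per lineage).
#' @param lineages character vector of semicolon-delimited lineages.
#' @return a `taxonomy_tree`: a `data.frame` with columns `id`, `name`,
#'   `rank`, `parent`, rooted at the synthetic node `"root"`.
#' @export
taxonomy_from_lineages <- function(ids, lineages) {
  if (length(ids) != length(lineages)) stop("ids and lineages lengths differ")
  if (anyDuplicated(ids))
    stop("conflicting definitions for node id '", ids[duplicated(ids)][1], "'")
  nodes <- data.frame(id = "root", name = "root", rank = "root",
                      parent = NA_character_, stringsAsFactors = FALSE)
  add_node <- function(id, name, rank, parent) {
    hit <- which(nodes$id == id)
    if (length(hit) == 1) {
      if (nodes$parent[hit] != parent || nodes$rank[hit] != rank)
        stop("conflicting parents for node id '", id, "'")
      return(invisible(NULL))
    }
    nodes[nrow(nodes) + 1, ] <<- list(id, name, rank, parent)
    invisible(NULL)
  }
  for (k in seq_along(ids)) {
    parts <- trimws(strsplit(lineages[k], ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) stop("empty lineage for taxon '", ids[k], "'")
    if (length(parts) > 5)
      stop("lineage for taxon '", ids[k], "' has more than 5 ranks")
    parent <- "root"
    # all but the last name are internal nodes keyed by name
    if (length(parts) > 1) {
      for (r in seq_len(length(parts) - 1)) {
        add_node(parts[r], parts[r], TAX_RANKS[r + 1], parent)
        parent <- parts[r]
      }
    }
    add_node(ids[k], parts[length(parts)], TAX_RANKS[length(parts) + 1], parent)
  }
  class(nodes) <- c("taxonomy_tree", "data.frame")
  validate_taxonomy(nodes)
}

#' Read a taxonomy lineage table
#'
#' Tab-separated rows: taxon id, semicolon-delimited ranked lineage.
#'
#' @param path path to the lineage file.
#' @return a `taxonomy_tree` (see [taxonomy_from_lineages()]).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(lines) > 0 && any(nf < 2))
    stop("taxonomy line ", which(nf < 2)[1], ": expected id<TAB>lineage")
  taxonomy_from_lineages(vapply(fields, `[[`, character(1), 1L),
                         vapply(fields, `[[`, character(1), 2L))
}

#' @noRd
validate_taxonomy <- function(tree) {
  if (sum(is.na(tree$parent)) != 1 || tree$id[is.na(tree$parent)] != "root")
    stop("taxonomy must have the single root 'root'")
  for (id in tree$id[!is.na(tree$parent)]) {
    seen <- character(0)
    cur <- id
    while (cur != "root") {
      if (cur %in% seen) stop("cycle in taxonomy at node '", id, "'")
      seen <- c(seen, cur)
      hit <- which(tree$id == cur)
      if (length(hit) != 1) stop("unknown parent '", cur, "' in taxonomy")
      cur <- tree$parent[hit]
    }
  }
  tree
}

# Path from root to `id`, inclusive.
#' @noRd
tax_ancestry <- function(tree, id) {
  path <- character(0)
  cur <- id
  repeat {
    hit <- which(tree$id == cur)
    if (length(hit) != 1) stop("unknown taxonomy node '", cur, "'")
    path <- c(cur, path)
    if (is.na(tree$parent[hit])) break
    cur <- tree$parent[hit]
  }
  path
}

# Lowest common ancestor of a set of node ids.
#' @noRd
tax_lca <- function(tree, ids) {
  ids <- unique(ids)
  paths <- lapply(ids, function(i) tax_ancestry(tree, i))
  k <- min(lengths(paths))
  lca <- "root"
  for (depth in seq_len(k)) {
    level <- vapply(paths, `[[`, character(1), depth)
    if (length(unique(level)) == 1) lca <- level[1] else break
  }
  lca
}
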