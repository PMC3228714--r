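#' Read a BLAST-tabular hit table
#'
#' Reads the 4-column tab-separated subset of BLAST tabular output used by
#' the taxonomy stage: query id, subject taxon id, bit score, E-value.
#' Extra columns are ignored. Hits with E-value above `max_evalue` are
#' dropped, and at most `top_k` hits per query are kept, ranked by
#' descending bit score (ties broken by subject id for stability).
#'
#' @param path path to the tab-separated hit table (no header).
#' @param max_evalue E-value ceiling; hits above it are discarded.
#' @param top_k maximum number of hits retained per query.
#' @return a named list (one element per query, in first-seen order) of
#'   `data.frame`s with columns `subject_taxon`, `bit_score`, `evalue`,
#'   sorted by descending `bit_score`.
#' @export
read_hit_table <- function(path, max_evalue = 1e-5, top_k = 25L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("hit table line ", which(nf < 4)[1], ": fewer than 4 fields")
  q <- vapply(fields, `[[`, character(1), 1L)
  s <- vapply(fields, `[[`, character(1), 2L)
  bit <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(bit))
    stop("hit table line ", which(is.na(bit))[1], ": non-numeric bit score")
  if (anyNA(ev))
    stop("hit table line ", which(is.na(ev))[1], ": non-numeric E-value")
  if (any(bit < 0)) stop("negative bit score in hit table")
  keep <- ev <= max_evalue
  q <- q[keep]; s <- s[keep]; bit <- bit[keep]; ev <- ev[keep]
  out <- list()
  for (qq in unique(q)) {
    i <- which(q == qq)
    i <- i[lex_order(-bit[i], s[i])]
    i <- head(i, top_k)
    out[[qq]] <- data.frame(subject_taxon = s[i], bit_score = bit[i],
                            evalue = ev[i], stringsAsFactors = FALSE)
  }
  out
}

#' Write per-query hits as a 4-column BLAST-tabular file
#'
#' @param hits a named list of hit `data.frame`s as returned by
#'   [read_hit_table()] or [toy_hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  rows <- character(0)
  for (qq in names(hits)) {
    h <- hits[[qq]]
    if (nrow(h) > 0)
      rows <- c(rows, paste(qq, h$subject_taxon,
                            format(h$bit_score, trim = TRUE, scientific = FALSE),
                            format(h$evalue, trim = TRUE), sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
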