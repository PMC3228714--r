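#' Write a distance matrix as a phylip lower-triangle file
#'
#' First line is the sequence count; each following line is a sequence id
#' followed by its distances to all earlier sequences, to six decimals.
#'
#' @param d a symmetric numeric matrix with zero diagonal and ids as
#'   `dimnames`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(d, path) {
  validate_dist_matrix(d)
  ids <- rownames(d)
  n <- nrow(d)
  lines <- character(n + 1)
  lines[1] <- as.character(n)
  for (i in seq_len(n)) {
    if (i == 1) lines[i + 1] <- ids[i]
    else lines[i + 1] <- paste(ids[i],
                               paste(sprintf("%.6f", d[i, seq_len(i - 1)]),
                                     collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a phylip lower-triangle distance matrix
#'
#' @param path path written by [write_dist_phylip()].
#' @return a symmetric numeric matrix with ids as `dimnames`.
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("phylip matrix: first line must be the sequence count")
  if (length(lines) != n + 1)
    stop("phylip matrix: expected ", n, " rows, found ", length(lines) - 1)
  ids <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(f) != i) stop("phylip matrix row ", i, ": expected ", i,
                             " fields, found ", length(f))
    ids[i] <- f[1]
    if (i > 1) {
      v <- as.numeric(f[-1])
      if (anyNA(v)) stop("phylip matrix row ", i, ": non-numeric distance")
      d[i, seq_len(i - 1)] <- v
      d[seq_len(i - 1), i] <- v
    }
  }
  dimnames(d) <- list(ids, ids)
  d
}

#' @noRd
validate_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must carry ids as dimnames")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0 | d > 1)) stop("distances must lie in [0, 1]")
  invisible(d)
}
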