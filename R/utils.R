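# Internal helpers shared across modules.

# IUPAC nucleotide ambiguity codes and the base sets they stand for.
IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

VALID_REGIONS <- c("V1V2", "V6", "unknown")

#' @noRd
iupac_regex <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s) in sequence: ", paste(bad, collapse = ", "))
  paste0(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

# Derive a reproducible sub-stream seed from a master seed and labels.
# Keeps results invariant to the order in which other streams are consumed.
#' @noRd
stream_seed <- function(seed, ...) {
  parts <- as.character(unlist(list(...)))
  h <- as.double(seed) %% 2147483629
  for (p in parts) {
    for (k in utf8ToInt(p)) h <- (h * 131 + k) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# C-locale (radix) ordering used for all lexicographic tie-breaks.
#' @noRd
lex_order <- function(...) order(..., method = "radix")

#' @noRd
random_dna <- function(length) {
  paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' @noRd
check_region <- function(region) {
  if (!region %in% VALID_REGIONS)
    stop("unknown region '", region, "'; expected one of ",
         paste(VALID_REGIONS, collapse = ", "))
  region
}
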