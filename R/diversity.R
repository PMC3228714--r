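#' Bias-corrected Chao1 richness estimate with 95% confidence interval
#'
#' Point estimate `Sobs + n1(n1-1) / (2(n2+1))`, where `n1` and `n2` are
#' the singleton and doubleton counts. The interval is the log-normal
#' construction on the variance of the estimated number of unseen
#' species, with the three-case variance (n1>0 & n2>0; n1>0 & n2=0;
#' n1=0). With no singletons the estimate carries no unseen mass and the
#' interval collapses to `(Sobs, Sobs)`.
#'
#' @param counts per-OTU read counts (positive integers).
#' @param bias_corrected use the bias-corrected form (default); `FALSE`
#'   gives the classic `Sobs + n1^2/(2 n2)` form (undefined when n2 = 0).
#' @return a list with `chao1`, `lci95`, `hci95`, `sobs`, `n1`, `n2`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty abundance vector")
  if (any(counts < 1)) stop("OTU counts must be >= 1")
  sobs <- length(counts)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  if (bias_corrected) {
    est <- sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
  } else {
    if (n2 == 0) stop("classic Chao1 is undefined when n2 = 0")
    est <- sobs + n1^2 / (2 * n2)
  }
  if (n1 == 0) {
    return(list(chao1 = sobs, lci95 = sobs, hci95 = sobs,
                sobs = sobs, n1 = n1, n2 = n2))
  }
  if (n2 > 0) {
    v <- n1 * (n1 - 1) / (2 * (n2 + 1)) +
      n1 * (2 * n1 - 1)^2 / (4 * (n2 + 1)^2) +
      n1^2 * n2 * (n1 - 1)^2 / (4 * (n2 + 1)^4)
  } else {
    v <- n1 * (n1 - 1) / 2 + n1 * (2 * n1 - 1)^2 / 4 - n1^4 / (4 * est)
  }
  t_unseen <- est - sobs
  if (t_unseen <= 0 || v <= 0) {
    return(list(chao1 = est, lci95 = sobs, hci95 = est,
                sobs = sobs, n1 = n1, n2 = n2))
  }
  k <- exp(1.96 * sqrt(log(1 + v / t_unseen^2)))
  list(chao1 = est, lci95 = sobs + t_unseen / k, hci95 = sobs + t_unseen * k,
       sobs = sobs, n1 = n1, n2 = n2)
}

#' Shannon diversity index
#'
#' `H = -sum (c_i/N) ln(c_i/N)`, natural logarithm.
#'
#' @param counts per-OTU read counts.
#' @return the Shannon index.
#' @export
shannon <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty abundance vector")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Subsample-normalized Shannon index
#'
#' Draws `reps` uniform subsamples of `size` reads without replacement,
#' computes the Shannon index of the OTU abundance vector each subsample
#' induces, and returns the mean. Each replicate consumes its own derived
#' RNG stream, so results are reproducible and order-independent given
#' the seed.
#'
#' @param labels per-read OTU labels (one element per read).
#' @param size subsample size (at most the number of reads).
#' @param reps number of subsamples (default 100).
#' @param seed RNG seed.
#' @return mean Shannon index across subsamples.
#' @export
normalized_shannon <- function(labels, size, reps = 100L, seed = 1L) {
  n <- length(labels)
  if (size > n) stop("subsample size exceeds the number of reads")
  if (reps < 1) stop("reps must be >= 1")
  h <- numeric(reps)
  for (r in seq_len(reps)) {
    sub <- with_seed(stream_seed(seed, "subsample", r),
                     sample(labels, size, replace = FALSE))
    h[r] <- shannon(as.numeric(table(sub)))
  }
  mean(h)
}

#' Analytic rarefaction: expected OTU richness at given depths
#'
#' Hypergeometric expectation
#' `E[S(m)] = Sobs - sum_i C(N - c_i, m) / C(N, m)`, evaluated in log
#' space for stability.
#'
#' @param counts per-OTU read counts.
#' @param depths subsample depths (each at most `N = sum(counts)`).
#' @return a `data.frame` with columns `depth` and `expected_otus`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty abundance vector")
  n <- sum(counts)
  if (any(depths < 0 | depths > n)) stop("depths must lie in [0, N]")
  sobs <- length(counts)
  expected <- vapply(depths, function(m) {
    if (m == 0) return(0)
    miss <- exp(lchoose(n - counts, m) - lchoose(n, m))
    sobs - sum(miss)
  }, numeric(1))
  data.frame(depth = as.integer(depths), expected_otus = expected)
}

#' Diversity summary of an OTU partition
#'
#' @param partition an `otu_partition` from [hier_cluster()].
#' @param subsample_size size for the normalized Shannon index; `NULL`
#'   uses the full read count (making it equal the plain Shannon index).
#' @param subsample_reps replicates for the normalized Shannon index.
#' @param seed RNG seed for subsampling.
#' @return a list with `chao1` (list), `shannon`,
#'   `shannon_normalized`, `subsample_size`, `subsample_reps`.
#' @export
diversity_estimate <- function(partition, subsample_size = NULL,
                               subsample_reps = 100L, seed = 1L) {
  counts <- partition$cluster_counts
  ch <- chao1(counts)
  h <- shannon(counts)
  n <- sum(counts)
  if (is.null(subsample_size)) subsample_size <- n
  labels <- rep(seq_along(counts), counts)
  hn <- normalized_shannon(labels, size = subsample_size,
                           reps = subsample_reps, seed = seed)
  list(chao1 = ch, shannon = h, shannon_normalized = hn,
       subsample_size = as.integer(subsample_size),
       subsample_reps = as.integer(subsample_reps))
}
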