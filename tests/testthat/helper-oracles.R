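# Independent reference implementations used as oracles. These never call
# the code paths they check.

# Exhaustive alignment oracle: enumerates every decomposition of a global
# alignment into (leading end-gap skip) + (core alignment, all gap columns
# internal) + (trailing end-gap skip), with the core's achievable
# (mismatch, internal-gap) pairs computed by a set-valued recursion over
# prefixes. Terminal gap runs are free; score = matches - mismatches -
# 2 * internal gap columns. Decompositions that mislabel a terminal gap
# column as internal only over-penalize, so the returned maximum score and
# the distance set of maximum-score alignments are exact.
brute_force_align <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  res_score <- numeric(0); res_mm <- integer(0)
  res_ig <- integer(0); res_cc <- integer(0)

  leads <- rbind(c(0L, 0L),
                 if (n > 0) cbind(seq_len(n), 0L),
                 if (m > 0) cbind(0L, seq_len(m)))
  for (L in seq_len(nrow(leads))) {
    la <- leads[L, 1]; lb <- leads[L, 2]
    A <- if (la < n) ca[(la + 1):n] else character(0)
    B <- if (lb < m) cb[(lb + 1):m] else character(0)
    p <- length(A); q <- length(B)
    # codes encode (mm, ig) as mm * 1000 + ig
    S <- vector("list", p + 1)
    for (i in 0:p) S[[i + 1]] <- vector("list", q + 1)
    S[[1]][[1]] <- 0L
    for (i in 0:p) for (j in 0:q) {
      if (i == 0 && j == 0) next
      acc <- integer(0)
      if (i > 0 && j > 0)
        acc <- c(acc, S[[i]][[j]] + if (A[i] != B[j]) 1000L else 0L)
      if (i > 0) acc <- c(acc, S[[i]][[j + 1]] + 1L)
      if (j > 0) acc <- c(acc, S[[i + 1]][[j]] + 1L)
      S[[i + 1]][[j + 1]] <- unique(acc)
    }
    read_cell <- function(i, j) {
      codes <- S[[i + 1]][[j + 1]]
      if (length(codes) == 0) return()
      mm <- codes %/% 1000L; ig <- codes %% 1000L
      diagn <- (i + j - ig) / 2
      cc <- diagn + ig
      sc <- diagn - 2 * mm - 2 * ig
      res_score <<- c(res_score, sc)
      res_mm <<- c(res_mm, mm); res_ig <<- c(res_ig, ig)
      res_cc <<- c(res_cc, cc)
    }
    for (ta in 0:p) read_cell(p - ta, q)
    if (q > 0) for (tb in 1:q) read_cell(p, q - tb)
  }
  best <- max(res_score)
  opt <- which(res_score == best)
  dists <- ifelse(res_cc[opt] == 0, 0,
                  (res_mm[opt] + res_ig[opt]) / res_cc[opt])
  list(score = best, dists = sort(unique(dists)))
}

# From-scratch agglomerative clustering oracle: recomputes every
# inter-cluster criterion from the original distance matrix at each step
# (no incremental updates), with the same tie-break (lowest pair of
# smallest member indices) and emit-at-cutoff semantics as the package.
naive_agglomerate <- function(d, counts, linkage, cutoffs, weighted = TRUE) {
  n <- nrow(d)
  w <- if (weighted) as.numeric(counts) else rep(1, n)
  members <- as.list(seq_len(n))
  pending <- sort(unique(cutoffs))
  parts <- list()
  crit <- function(A, B) {
    sub <- d[A, B, drop = FALSE]
    switch(linkage,
           single = min(sub),
           complete = max(sub),
           average = sum(outer(w[A], w[B]) * sub) / (sum(w[A]) * sum(w[B])))
  }
  canon <- function(members) {
    ord <- order(vapply(members, min, integer(1)))
    assign <- integer(n)
    for (k in seq_along(ord)) assign[members[[ord[k]]]] <- k
    assign
  }
  while (length(members) > 1) {
    best <- Inf; bi <- 0L; bj <- 0L; bkey <- c(Inf, Inf)
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        v <- crit(members[[i]], members[[j]])
        key <- sort(c(min(members[[i]]), min(members[[j]])))
        better <- v < best ||
          (v == best && (key[1] < bkey[1] ||
                         (key[1] == bkey[1] && key[2] < bkey[2])))
        if (better) { best <- v; bi <- i; bj <- j; bkey <- key }
      }
    }
    while (length(pending) > 0 && best > pending[1]) {
      parts[[as.character(pending[1])]] <- canon(members)
      pending <- pending[-1]
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  for (cut in pending) parts[[as.character(cut)]] <- canon(members)
  parts
}

# Random symmetric distance matrix with unit diagonal structure.
random_dist_matrix <- function(n, ids = sprintf("s%02d", seq_len(n))) {
  d <- matrix(0, n, n)
  v <- runif(n * (n - 1) / 2)
  d[lower.tri(d)] <- v
  d <- d + t(d)
  dimnames(d) <- list(ids, ids)
  d
}

# Exhaustive rarefaction: mean observed richness over all subsets of the
# read multiset at a given depth.
exhaustive_rarefaction <- function(counts, depth) {
  labels <- rep(seq_along(counts), counts)
  subs <- utils::combn(seq_along(labels), depth)
  mean(apply(subs, 2, function(idx) length(unique(labels[idx]))))
}
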