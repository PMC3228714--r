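test_that("precluster absorbs near-identical entries into abundant seeds", {
  base <- strrep("GATCCGTA", 8)
  b <- substitute_at(base, 3)                 # 1 diff from base
  dr <- make_derep(c(base, b), c(10L, 2L))
  out <- precluster(dr, max_diffs = 2)
  expect_equal(unique_otus(out), 1L)
  expect_equal(out$count, 12L)
  expect_equal(out$seq, base)

  c3 <- substitute_at(base, c(3, 20, 40))     # 3 diffs: beyond the max of 2
  dr2 <- make_derep(c(base, c3), c(10L, 2L))
  out2 <- precluster(dr2, max_diffs = 2)
  expect_equal(unique_otus(out2), 2L)
})

test_that("preclustering is single-pass against retained seeds", {
  base <- strrep("GATCCGTA", 8)
  a <- base
  b <- substitute_at(base, c(1, 2))            # 2 diffs from A
  c <- substitute_at(base, c(1, 2, 17, 18))    # 2 from B, 4 from A
  dr <- make_derep(c(a, b, c), c(10L, 5L, 1L))
  out <- precluster(dr, max_diffs = 2)
  # B joins A; C is compared to the seed A (4 diffs), not to B, so it stands
  expect_equal(unique_otus(out), 2L)
  expect_equal(out$count[out$seq == a], 15L)
  expect_equal(out$count[out$seq == c], 1L)
})

test_that("two sequences cluster together exactly when within the cutoff", {
  for (linkage in c("single", "average", "complete")) {
    d <- matrix(c(0, 0.02, 0.02, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    p <- hier_cluster(d, c(5L, 3L), linkage, 0.03)[[1]]
    expect_equal(p$n_otus, 1L)
    expect_equal(p$cluster_counts, 8L)

    d[1, 2] <- d[2, 1] <- 0.05
    p2 <- hier_cluster(d, c(5L, 3L), linkage, 0.03)[[1]]
    expect_equal(p2$n_otus, 2L)
  }
})

test_that("hierarchical clustering matches the from-scratch agglomerator", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(4:12, 1)
    d <- random_dist_matrix(n)
    counts <- sample(1:30, n, replace = TRUE)
    linkage <- sample(c("single", "average", "complete"), 1)
    cuts <- sort(runif(2, 0.05, 0.9))
    got <- hier_cluster(d, counts, linkage, cuts)
    want <- naive_agglomerate(d, counts, linkage, cuts)
    for (cut in names(want)) {
      expect_equal(unname(got[[cut]]$assignment), want[[cut]],
                   info = paste(linkage, "cutoff", cut, "trial", trial))
    }
  }
})

test_that("tied merge criteria are resolved toward the lowest id pair", {
  # three sequences all 0.1 apart: (1,2) must merge first
  d <- matrix(0.1, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(d) <- 0
  got <- hier_cluster(d, c(1L, 1L, 1L), "single", 0.15)[[1]]
  want <- naive_agglomerate(d, c(1L, 1L, 1L), "single", 0.15)[["0.15"]]
  expect_equal(unname(got$assignment), want)
  expect_equal(got$n_otus, 1L)
})

test_that("OTU counts are non-increasing in the cutoff", {
  set.seed(32)
  for (trial in 1:5) {
    d <- random_dist_matrix(15)
    counts <- sample(1:20, 15, replace = TRUE)
    parts <- hier_cluster(d, counts, "average", c(0.03, 0.06, 0.10, 0.3, 0.6))
    ns <- vapply(parts, function(p) p$n_otus, integer(1))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("extreme cutoffs give one cluster or all singletons", {
  set.seed(33)
  d <- random_dist_matrix(10) * 0.5 + 0.2
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  dimnames(d) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  counts <- rep(1L, 10)
  for (linkage in c("single", "average", "complete")) {
    hi <- hier_cluster(d, counts, linkage, 0.99)[[1]]
    expect_equal(hi$n_otus, 1L)
    lo <- hier_cluster(d, counts, linkage,
                       min(d[upper.tri(d)]) * 0.5)[[1]]
    expect_equal(lo$n_otus, 10L)
  }
})

test_that("complete-linkage clusters respect the cutoff diameter", {
  set.seed(34)
  d <- random_dist_matrix(14)
  p <- hier_cluster(d, rep(1L, 14), "complete", 0.35)[[1]]
  for (k in seq_len(p$n_otus)) {
    idx <- which(p$assignment == k)
    if (length(idx) > 1)
      expect_lte(max(d[idx, idx]), 0.35)
  }
})

test_that("cluster read counts are conserved and unique_otus is cutoff zero", {
  dr <- make_derep(c("AAAA", "TTTT", "GGGG"), c(4L, 2L, 1L))
  expect_equal(unique_otus(dr), 3L)
  d <- pairwise_distance_matrix(dr)
  p <- hier_cluster(d, dr$count, "average", 0.5)[[1]]
  expect_equal(sum(p$cluster_counts), 7L)
})

test_that("weighted and unweighted average linkage can disagree", {
  # a heavy sequence pulls the merged criterion toward its own distances
  d <- matrix(0, 4, 4)
  d[1, 2] <- 0.02; d[1, 3] <- 0.10; d[2, 3] <- 0.35; d[1, 4] <- 0.9
  d[2, 4] <- 0.9; d[3, 4] <- 0.9
  d <- d + t(d)
  dimnames(d) <- list(letters[1:4], letters[1:4])
  counts <- c(100L, 1L, 1L, 1L)
  w <- hier_cluster(d, counts, "average", 0.2, weighted = TRUE)[[1]]
  u <- hier_cluster(d, counts, "average", 0.2, weighted = FALSE)[[1]]
  # weighted: {a,b} to c is ~0.10; unweighted: ~0.225 blocks the merge
  expect_equal(w$n_otus, 2L)
  expect_equal(u$n_otus, 3L)
})
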