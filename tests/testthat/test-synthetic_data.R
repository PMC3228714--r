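test_that("template generation honours the pairwise divergence floor", {
  one <- generate_templates(1, 100, 0.05, seed = 1)
  expect_equal(length(one), 1L)
  expect_equal(nchar(one[[1]]), 100L)

  two <- generate_templates(2, 300, 0.10, seed = 2)
  expect_gte(seq_distance(two[[1]], two[[2]]), 0.10)

  tpl <- generate_templates(20, 300, 0.05, seed = 7)
  d <- pairwise_distance_matrix(tpl)
  expect_gte(min(d[upper.tri(d)]), 0.05)
  # deterministic given the seed
  expect_identical(generate_templates(20, 300, 0.05, seed = 7), tpl)
})

test_that("new templates can be forced divergent from an existing set", {
  tpl <- generate_templates(6, 280, 0.05, seed = 3)
  extra <- generate_templates(3, 280, 0.05, seed = 4,
                              backbone = attr(tpl, "backbone"),
                              exclude = tpl)
  cross <- outer(extra, tpl, Vectorize(seq_distance))
  expect_gte(min(cross), 0.05)
})

test_that("infeasible template requests fail after bounded retries", {
  expect_error(generate_templates(50, 12, 0.9, seed = 5, max_tries = 3),
               "could not place template")
})

test_that("geometric abundances reproduce the dominant-genus regime", {
  expect_equal(sample_abundances(1, 0.5), 1)
  expect_equal(sample_abundances(4, 1), rep(0.25, 4))
  p <- sample_abundances(10, 0.25)
  expect_gte(p[1], 0.75)   # rank-1 template dominates
  expect_equal(sum(p), 1)
  expect_true(all(diff(p) < 0))
})

test_that("noiseless reads are identical copies of primer + template", {
  tpl <- generate_templates(1, 120, 0.05, seed = 11)
  cm <- community_model(tpl, region = "V1V2")
  g <- generate_reads(cm, 10, error_model(), V1V2_FWD(), seed = 6)
  expect_equal(nrow(g$reads), 10L)
  expect_equal(length(unique(g$reads$seq)), 1L)
  expect_true(endsWith(g$reads$seq[1], tpl[[1]]))
  expect_equal(nchar(g$reads$seq[1]), 39L + 120L)
  expect_true(all(g$truth$errors == 0))
  # the resolved primer still satisfies the exact IUPAC split
  expect_equal(nrow(split_by_primer(g$reads, default_primers())$V1V2), 10L)
})

test_that("forced homopolymer indels always change the run length", {
  tpl <- setNames("ACGTACGCGTAAACGTACGCTACGATCG", "T001")  # one AAA run
  cm <- community_model(tpl, region = "V1V2")
  g <- generate_reads(cm, 30, error_model(hp_indel_rate = 1), V1V2_FWD(),
                      seed = 8)
  expect_false(any(grepl("GTAAACG", g$reads$seq)))
  expect_true(all(g$truth$errors >= 1))
})

test_that("template sampling frequencies follow the abundances", {
  tpl <- generate_templates(10, 200, 0.05, seed = 12)
  p <- sample_abundances(10, 0.5)
  cm <- community_model(tpl, p, region = "V1V2")
  g <- generate_reads(cm, 5000, error_model(), V1V2_FWD(), seed = 13)
  obs <- table(factor(g$truth$template_id, levels = names(tpl)))
  se <- sqrt(5000 * p * (1 - p))
  expect_true(all(abs(as.numeric(obs) - 5000 * p) <= 3 * se + 1e-9))
})

test_that("contamination spikes are sized and flagged exactly", {
  tpl <- generate_templates(4, 220, 0.05, seed = 14)
  cm <- community_model(tpl, region = "V1V2")
  base <- generate_reads(cm, 9900, error_model(), V1V2_FWD(), seed = 15)
  ctl_tpl <- generate_templates(2, 220, 0.05, seed = 16,
                                backbone = attr(tpl, "backbone"),
                                exclude = tpl)
  names(ctl_tpl) <- c("C001", "C002")
  ctl <- community_model(ctl_tpl, region = "V1V2")

  none <- spike_contamination(base$reads, ctl, 0, error_model(), V1V2_FWD(),
                              seed = 17)
  expect_equal(none$sample, base$reads)
  expect_gt(nrow(none$control), 0L)

  spiked <- spike_contamination(base$reads, ctl, 0.01, error_model(),
                                V1V2_FWD(), seed = 17)
  expect_equal(nrow(spiked$sample) - nrow(base$reads), 100L)  # 100/10000
  expect_equal(nrow(spiked$truth), 100L)
  expect_true(all(spiked$truth$contaminant))
})

test_that("fixing the seed fixes every emitted byte", {
  tpl <- generate_templates(5, 150, 0.05, seed = 18)
  cm <- community_model(tpl, sample_abundances(5, 0.4), region = "V1V2")
  err <- error_model(sub_rate = 0.01, hp_indel_rate = 0.02)
  g1 <- generate_reads(cm, 300, err, V1V2_FWD(), seed = 19)
  g2 <- generate_reads(cm, 300, err, V1V2_FWD(), seed = 19)
  expect_identical(g1, g2)
  g3 <- generate_reads(cm, 300, err, V1V2_FWD(), seed = 20)
  expect_false(identical(g1$reads$seq, g3$reads$seq))
})
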