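make_v1v2_read <- function(tail_len = 250, id = "r1", seed = NULL) {
  # M in the V1V2 target may resolve to A or C on the molecule
  seq <- paste0("GCCTCCCTCGCGCCATCAG", "AGAGTTTGATCATGGCTCAG",
                strrep("ACGT", ceiling(tail_len / 4)))
  sequence_records(id, substr(seq, 1, 39 + tail_len))
}

test_that("reads split on exact primer match with IUPAC codes in the primer", {
  primers <- default_primers()
  r <- make_v1v2_read()
  out <- split_by_primer(r, primers)
  expect_equal(nrow(out$V1V2), 1L)
  expect_equal(attr(out, "discarded"), 0L)

  # one mismatch in the target kills the exact match
  bad <- r
  bad$seq <- sub("AGAGTTTGATC", "AGAGTTTGTTC", bad$seq)
  out <- split_by_primer(bad, primers)
  expect_equal(nrow(out$V1V2), 0L)
  expect_equal(attr(out, "discarded"), 1L)

  # ambiguity matching is one-directional: an N in the read does not
  # satisfy the primer's M at that position
  amb <- r
  substr(amb$seq, 31, 31) <- "N"
  out <- split_by_primer(amb, primers)
  expect_equal(attr(out, "discarded"), 1L)
})

test_that("a mixed pool splits into regions with garbled reads discarded", {
  primers <- default_primers()
  v1 <- paste0("GCCTCCCTCGCGCCATCAG", "AGAGTTTGATCCTGGCTCAG", strrep("AC", 130))
  v6 <- paste0("GCCTCCCTCGCGCCATCAG", "CGACACGAGCTGACGAC", strrep("GT", 130))
  junk <- strrep("TG", 140)
  reads <- sequence_records(sprintf("r%03d", 1:100),
                            c(rep(v1, 60), rep(v6, 30), rep(junk, 10)))
  out <- split_by_primer(reads, primers)
  expect_equal(nrow(out$V1V2), 60L)
  expect_equal(nrow(out$V6), 30L)
  expect_equal(attr(out, "discarded"), 10L)
  expect_true(all(out$V1V2$region == "V1V2"))
})

test_that("length cutoffs are inclusive at 218 (V1V2) and 235 (V6)", {
  p1 <- V1V2_FWD()
  for (n in c(217, 218, 240)) {
    r <- make_v1v2_read(tail_len = n)
    got <- trim_and_filter(r, p1)
    if (n >= 218) {
      expect_equal(nrow(got), 1L)
      expect_equal(nchar(got$seq), n)  # primer trimmed off
      expect_false(startsWith(got$seq, "GCCTCC"))
    } else {
      expect_equal(nrow(got), 0L)
    }
  }
  p6 <- V6_FWD()
  base <- paste0(p6$adapter, p6$target)
  for (n in c(234, 235)) {
    r <- sequence_records("x", paste0(base, strrep("A", n)))
    got <- trim_and_filter(r, p6)
    expect_equal(nrow(got), if (n >= 235) 1L else 0L)
  }
})

test_that("dereplication merges identical reads and conserves counts", {
  reads <- sequence_records(c("a", "b", "c"), c("ACGT", "ACGT", "ACGA"))
  dr <- dereplicate(reads)
  expect_equal(dr$id, c("a", "c"))  # representative = first occurrence
  expect_equal(dr$count, c(2L, 1L))
  expect_equal(dr$members, list(c("a", "b"), "c"))

  distinct <- sequence_records(c("x", "y"), c("AAAA", "TTTT"))
  dr2 <- dereplicate(distinct)
  expect_equal(dr2$id, c("x", "y"))
  expect_equal(dr2$count, c(1L, 1L))

  expect_equal(unique_otus(dereplicate(distinct[0, ])), 0L)
})

test_that("denoise absorbs rare neighbours into abundant seeds", {
  base <- strrep("ACGTGCTA", 10)
  near <- substitute_at(base, 5)          # 1 difference
  far <- substitute_at(base, c(5, 20, 40, 60, 70))  # 5 differences
  dr <- make_derep(c(base, near), c(50L, 2L))
  out <- denoise(dr, max_diffs = 2, hp_discount = FALSE)
  expect_equal(unique_otus(out), 1L)
  expect_equal(out$count, 52L)
  expect_equal(out$seq, base)

  dr2 <- make_derep(c(base, far), c(50L, 2L))
  out2 <- denoise(dr2, max_diffs = 2, hp_discount = FALSE)
  expect_equal(unique_otus(out2), 2L)
})

test_that("denoise is idempotent and conserves reads", {
  set.seed(9)
  backbone <- paste0(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
  seqs <- unique(c(backbone,
                   replicate(20, substitute_at(backbone,
                                               sample(90, sample(1:6, 1))))))
  counts <- sample(1:40, length(seqs), replace = TRUE)
  dr <- make_derep(seqs, counts)
  once <- denoise(dr)
  twice <- denoise(once)
  expect_equal(twice$seq, once$seq)
  expect_equal(twice$count, once$count)
  expect_equal(derep_reads(once), sum(counts))
})

test_that("the homopolymer discount halves indels at runs", {
  base <- "ACGTACAAATCGTACGCTGACGTACGT"   # one AAA run
  plus <- sub("AAA", "AAAA", base)        # hp insertion: 0.5 discounted
  dr <- make_derep(c(base, plus), c(10L, 1L))
  # one full difference would block a merge at radius 0.5 without discount
  merged <- denoise(dr, max_diffs = 0.5, hp_discount = TRUE)
  expect_equal(unique_otus(merged), 1L)
  unmerged <- denoise(dr, max_diffs = 0.5, hp_discount = FALSE)
  expect_equal(unique_otus(unmerged), 2L)
})

test_that("noiseless reads from divergent templates denoise to one entry each", {
  tpl <- generate_templates(10, 260, 0.05, seed = 21)
  cm <- community_model(tpl, sample_abundances(10, 0.6), region = "V1V2")
  g <- generate_reads(cm, 400, error_model(), V1V2_FWD(), seed = 4)
  tr <- trim_and_filter(split_by_primer(g$reads, default_primers())$V1V2,
                        V1V2_FWD())
  dn <- denoise(dereplicate(tr))
  expect_equal(unique_otus(dn), length(unique(g$truth$template_id)))
  # no merger may join reads of different templates
  rep_of <- setNames(rep(dn$id, lengths(dn$members)), unlist(dn$members))
  tmpl_of_entry <- tapply(g$truth$template_id[match(names(rep_of),
                                                    g$truth$read_id)],
                          rep_of, function(x) length(unique(x)))
  expect_true(all(tmpl_of_entry == 1))
})

test_that("pipeline counters must be non-increasing", {
  pc <- pipeline_counters(100, 90, 80, 80, 79)
  expect_equal(pc$after_decontam, 79)
  expect_error(pipeline_counters(100, 90, 95, 80, 79), "non-increasing")
})
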