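simple_tree <- function() {
  taxonomy_from_lineages(
    c("sp_lc", "sp_li", "sp_pb", "sp_gv"),
    c("Firmicutes;Lactobacillales;Lactobacillaceae;Lactobacillus;L crispatus",
      "Firmicutes;Lactobacillales;Lactobacillaceae;Lactobacillus;L iners",
      "Bacteroidetes;Bacteroidales;Prevotellaceae;Prevotella;P bivia",
      "Actinobacteria;Bifidobacteriales;Bifidobacteriaceae;Gardnerella;G vaginalis"))
}

hit <- function(taxon, score) {
  data.frame(subject_taxon = taxon, bit_score = score,
             evalue = 1e-20, stringsAsFactors = FALSE)
}

test_that("hits are replicated once per member read", {
  dr <- make_derep(c("AAAA", "TTTT"), c(3L, 1L))
  hits <- list()
  hits[[dr$id[1]]] <- hit(c("sp_lc", "sp_li"), c(150, 140))
  hits[[dr$id[2]]] <- hit("sp_pb", 120)
  rh <- replicate_hits(hits, dr)
  expect_equal(length(rh), 4L)              # every read has a list
  for (m in dr$members[[1]]) expect_equal(rh[[m]], hits[[dr$id[1]]])
  total_rows <- sum(vapply(rh, nrow, integer(1)))
  expect_equal(total_rows, 3 * 2 + 1 * 1)   # sum of count_i x hits_i

  expect_error(replicate_hits(list(zzz = hit("sp_lc", 10)), dr),
               "not a representative")
})

test_that("LCA assignment walks to the lowest shared node", {
  tree <- simple_tree()
  rh <- list(
    r1 = hit("sp_lc", 150),                          # species
    r2 = hit(c("sp_lc", "sp_li"), c(150, 150)),      # same genus
    r3 = hit(c("sp_lc", "sp_pb"), c(150, 150)),      # different phyla
    r4 = hit("sp_gv", 80),                           # below min score
    r5 = hit(c("sp_lc", "sp_pb"), c(200, 150)))      # outside top window
  a <- lca_assign(rh, tree)
  expect_equal(a$node[a$read_id == "r1"], "sp_lc")
  expect_equal(a$node[a$read_id == "r2"], "Lactobacillus")
  expect_equal(a$node[a$read_id == "r3"], "root")
  expect_equal(a$node[a$read_id == "r4"], "NoHits")
  expect_equal(a$node[a$read_id == "r5"], "sp_lc")

  wide <- lca_assign(rh["r5"], tree, top_percent = 1)
  expect_equal(wide$node, "root")

  # a read with no hit entry at all lands in NoHits
  a2 <- lca_assign(rh["r1"], tree, read_ids = c("r1", "orphan"))
  expect_equal(a2$node[a2$read_id == "orphan"], "NoHits")

  expect_error(lca_assign(list(r9 = hit("nope", 500)), tree),
               "unknown taxon")
})

test_that("the assigned node is an ancestor-or-self of every retained hit", {
  tree <- simple_tree()
  set.seed(81)
  taxa <- tree$id[tree$rank == "species"]
  for (trial in 1:20) {
    k <- sample(1:3, 1)
    h <- hit(sample(taxa, k), round(runif(k, 100, 300)))
    a <- lca_assign(list(r = h), tree)
    best <- max(h$bit_score)
    retained <- h$subject_taxon[h$bit_score >= 0.9 * best]
    for (tx in retained) {
      expect_true(a$node %in% uridiv:::tax_ancestry(tree, tx))
    }
  }
})

test_that("minimum support moves weak taxa to NotAssigned, boundary at 5", {
  tree <- simple_tree()
  nodes <- c(rep("sp_lc", 5), rep("sp_pb", 4), rep("NoHits", 2))
  a <- data.frame(read_id = sprintf("r%02d", seq_along(nodes)), node = nodes,
                  stringsAsFactors = FALSE)
  f <- apply_min_support(a, 5)
  expect_equal(sum(f$node == "sp_lc"), 5L)           # reported at 5 reads
  expect_equal(sum(f$node == "sp_pb"), 0L)           # 4 reads -> bucket
  expect_equal(sum(f$node == "NotAssigned"), 4L)
  expect_equal(sum(f$node == "NoHits"), 2L)          # untouched
  expect_equal(apply_min_support(a, 1), a)           # identity at 1
  expect_equal(nrow(f), nrow(a))                     # reads conserved
})

test_that("normalization scales tallies to the target and keeps proportions", {
  tree <- simple_tree()
  mk <- function(n_lc, n_pb) {
    data.frame(read_id = sprintf("r%03d", seq_len(n_lc + n_pb)),
               node = c(rep("sp_lc", n_lc), rep("sp_pb", n_pb)),
               stringsAsFactors = FALSE)
  }
  res <- normalize_and_summarize(list(A = mk(20, 30)), tree, target = 100000)
  expect_equal(res$tables$genus["Lactobacillus", "A"], 40000)
  expect_equal(res$tables$genus["Prevotella", "A"], 60000)
  expect_equal(res$tables$phylum["Firmicutes", "A"], 40000)
  expect_equal(res$counts$phyla, 2L)
  expect_equal(res$counts$genera, 2L)

  # proportional samples normalize to identical rows
  res2 <- normalize_and_summarize(list(A = mk(20, 30), B = mk(200, 300)),
                                  tree, target = 100000)
  expect_equal(res2$tables$genus[, "A"], res2$tables$genus[, "B"])
})

test_that("read bookkeeping sums across buckets at every stage", {
  tree <- simple_tree()
  nodes <- c(rep("sp_lc", 7), rep("sp_gv", 3), "NoHits", "NotAssigned")
  a <- data.frame(read_id = sprintf("r%02d", seq_along(nodes)), node = nodes,
                  stringsAsFactors = FALSE)
  f <- apply_min_support(a, 5)
  res <- normalize_and_summarize(list(S = f), tree)
  b <- res$buckets
  expect_equal(b$assigned + b$not_assigned + b$no_hits, nrow(a))
})

test_that("zero-error synthetic data is assigned to its true genera", {
  tpl <- generate_templates(6, 250, 0.06, seed = 91)
  tree <- toy_tree(6)
  sp_ids <- sprintf("sp%02d", 1:6)
  cm <- community_model(tpl, sample_abundances(6, 0.5),
                        taxa = setNames(sp_ids, names(tpl)),
                        region = "V1V2")
  g <- generate_reads(cm, 300, error_model(), V1V2_FWD(), seed = 92)
  dr <- dereplicate(trim_and_filter(
    split_by_primer(g$reads, default_primers())$V1V2, V1V2_FWD()))
  hits <- toy_hit_table(dr, cm)
  a <- lca_assign(replicate_hits(hits, dr), tree,
                  read_ids = unlist(dr$members))
  truth_sp <- cm$taxa[g$truth$template_id[match(a$read_id,
                                                g$truth$read_id)]]
  expect_equal(a$node, unname(truth_sp))

  # genus-level composition equals the simulated community exactly
  res <- normalize_and_summarize(list(S = a), tree)
  genus_of <- tree$parent[match(truth_sp, tree$id)]
  want <- table(genus_of) / length(genus_of) * 100000
  got <- res$tables$genus[names(want), "S"]
  expect_equal(unname(got), as.numeric(want))
})
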