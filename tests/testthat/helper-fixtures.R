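# Small fixture builders shared across test files.

V1V2_FWD <- function() default_primers()[1, ]
V6_FWD <- function() default_primers()[3, ]

# A derep_set built directly from sequences and counts.
make_derep <- function(seqs, counts, region = "V1V2",
                       ids = sprintf("r%03d", seq_along(seqs))) {
  members <- lapply(seq_along(seqs), function(k)
    sprintf("%s_m%03d", ids[k], seq_len(counts[k])))
  derep_set(id = ids, seq = seqs, count = as.integer(counts),
            members = members, region = region)
}

# Mutate `seq` by substituting the bases at 1-based positions `at`.
substitute_at <- function(seq, at) {
  chars <- strsplit(seq, "")[[1]]
  for (p in at) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste0(chars, collapse = "")
}

# A small ready-made community over a shared backbone, with taxonomy.
toy_community <- function(n = 6, seed = 42, shape = 0.5, length = 280,
                          min_div = 0.05, region = "V1V2") {
  tpl <- generate_templates(n, length, min_div, seed = seed)
  genera <- rep(c("Lactobacillus", "Prevotella", "Gardnerella"),
                length.out = n)
  phyla <- c(Lactobacillus = "Firmicutes", Prevotella = "Bacteroidetes",
             Gardnerella = "Actinobacteria")
  orders <- c(Lactobacillus = "Lactobacillales",
              Prevotella = "Bacteroidales",
              Gardnerella = "Bifidobacteriales")
  families <- c(Lactobacillus = "Lactobacillaceae",
                Prevotella = "Prevotellaceae",
                Gardnerella = "Bifidobacteriaceae")
  sp_ids <- sprintf("sp%02d", seq_len(n))
  lineages <- vapply(seq_len(n), function(k) {
    g <- genera[k]
    paste(phyla[[g]], orders[[g]], families[[g]], g,
          paste0(g, " species", k), sep = ";")
  }, character(1))
  tree <- taxonomy_from_lineages(sp_ids, lineages)
  community_model(tpl, sample_abundances(n, shape),
                  taxa = setNames(sp_ids, names(tpl)), region = region)
  # note: taxa names follow template ids T001..
}

toy_tree <- function(n = 6) {
  genera <- rep(c("Lactobacillus", "Prevotella", "Gardnerella"),
                length.out = n)
  phyla <- c(Lactobacillus = "Firmicutes", Prevotella = "Bacteroidetes",
             Gardnerella = "Actinobacteria")
  orders <- c(Lactobacillus = "Lactobacillales",
              Prevotella = "Bacteroidales",
              Gardnerella = "Bifidobacteriales")
  families <- c(Lactobacillus = "Lactobacillaceae",
                Prevotella = "Prevotellaceae",
                Gardnerella = "Bifidobacteriaceae")
  sp_ids <- sprintf("sp%02d", seq_len(n))
  lineages <- vapply(seq_len(n), function(k) {
    g <- genera[k]
    paste(phyla[[g]], orders[[g]], families[[g]], g,
          paste0(g, " species", k), sep = ";")
  }, character(1))
  taxonomy_from_lineages(sp_ids, lineages)
}
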