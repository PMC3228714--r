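#!/usr/bin/env Rscript
# Simulate the synthetic study: 8 individuals, two 16S amplicon regions
# (V1V2, V6), reagent contamination spiked at 1%, plus one negative
# extraction control per region. Reads and truth tables are written under
# scratch/sim/ (large, regenerable); the community design table goes to
# results/.
#
# Study design, emulating a small cohort of culture-negative urine
# specimens: per region a shared pool
# of 12 gene variants over one backbone; each individual carries a subset,
# six of the eight with a strongly dominated community (geometric shape
# 0.2, rank-1 share ~80%) and two with an even profile (shape 0.7).

suppressPackageStartupMessages(library(uridiv))

seed <- 20110957L
out_dir <- "scratch/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

primers <- default_primers()
regions <- list(
  V1V2 = list(primer = primers[1, ], tpl_len = 300L, n_reads = 800L),
  V6   = list(primer = primers[3, ], tpl_len = 250L, n_reads = 700L))

genera <- c("Lactobacillus", "Prevotella", "Gardnerella", "Streptococcus",
            "Staphylococcus", "Dialister", "Peptoniphilus", "Finegoldia",
            "Anaerococcus", "Allisonella", "Aerococcus", "Ureaplasma")
lineage_of <- c(
  Lactobacillus = "Firmicutes;Lactobacillales;Lactobacillaceae;Lactobacillus",
  Prevotella = "Bacteroidetes;Bacteroidales;Prevotellaceae;Prevotella",
  Gardnerella = "Actinobacteria;Bifidobacteriales;Bifidobacteriaceae;Gardnerella",
  Streptococcus = "Firmicutes;Lactobacillales;Streptococcaceae;Streptococcus",
  Staphylococcus = "Firmicutes;Bacillales;Staphylococcaceae;Staphylococcus",
  Dialister = "Firmicutes;Veillonellales;Veillonellaceae;Dialister",
  Peptoniphilus = "Firmicutes;Tissierellales;Peptoniphilaceae;Peptoniphilus",
  Finegoldia = "Firmicutes;Tissierellales;Peptoniphilaceae;Finegoldia",
  Anaerococcus = "Firmicutes;Tissierellales;Peptoniphilaceae;Anaerococcus",
  Allisonella = "Firmicutes;Veillonellales;Veillonellaceae;Allisonella",
  Aerococcus = "Firmicutes;Lactobacillales;Aerococcaceae;Aerococcus",
  Ureaplasma = "Tenericutes;Mycoplasmatales;Mycoplasmataceae;Ureaplasma")

err <- error_model(sub_rate = 0.002, hp_indel_rate = 0.005)
samples <- sprintf("F%d", 1:8)
dominated <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)

design_rows <- list()
lineage_rows <- character(0)

for (rg in names(regions)) {
  cfg <- regions[[rg]]
  pool <- generate_templates(12, cfg$tpl_len, 0.05,
                             seed = seed + match(rg, names(regions)))
  sp_ids <- sprintf("%s_sp%02d", rg, 1:12)
  names(pool) <- sprintf("%s_T%02d", rg, 1:12)
  lineage_rows <- c(lineage_rows, vapply(1:12, function(k) {
    g <- genera[k]
    paste0(sp_ids[k], "\t", lineage_of[[g]], ";", g, " sim-species ", k)
  }, character(1)))

  ctl_tpl <- generate_templates(2, cfg$tpl_len, 0.05,
                                seed = seed + 100 + match(rg, names(regions)),
                                backbone = attr(pool, "backbone"),
                                exclude = pool)
  names(ctl_tpl) <- sprintf("%s_reagent%02d", rg, 1:2)
  ctl_cm <- community_model(ctl_tpl, region = rg)

  control_written <- FALSE
  for (s in seq_along(samples)) {
    sid <- samples[s]
    k <- 4 + (s %% 5)  # 4-8 templates per individual
    set.seed(seed + 1000 * s + match(rg, names(regions)))
    pick <- sort(sample(12, k))
    shape <- if (dominated[s]) 0.2 else 0.7
    ab <- sample_abundances(k, shape)
    cm <- community_model(pool[pick], ab,
                          taxa = setNames(sp_ids[pick], names(pool)[pick]),
                          region = rg)
    g <- generate_reads(cm, cfg$n_reads, err, cfg$primer,
                        seed = seed + 10000 * s + match(rg, names(regions)),
                        sample = sid, id_prefix = paste0(sid, "_", rg))
    spk <- spike_contamination(g$reads, ctl_cm, 0.01, err, cfg$primer,
                               seed = seed + 20000 * s +
                                 match(rg, names(regions)),
                               n_control_reads = 400L)
    write_fasta(spk$sample, file.path(out_dir,
                                      sprintf("%s_%s.fasta", sid, rg)))
    write_truth(rbind(g$truth, spk$truth),
                file.path(out_dir, sprintf("%s_%s_truth.tsv", sid, rg)))
    if (!control_written) {
      write_fasta(spk$control, file.path(out_dir,
                                         sprintf("control_%s.fasta", rg)))
      control_written <- TRUE
    }
    design_rows[[paste(sid, rg)]] <- data.frame(
      sample = sid, region = rg, templates = k,
      shape = shape, reads = nrow(spk$sample),
      spiked = nrow(spk$truth), stringsAsFactors = FALSE)
    message(sprintf("simulated %s %s: %d reads (%d spiked)", sid, rg,
                    nrow(spk$sample), nrow(spk$truth)))
  }

  # reference database for taxonomic assignment: the pooled gene variants
  # named by their species node ids
  ref <- sequence_records(sp_ids, unname(pool), region = rg)
  write_fasta(ref, file.path(out_dir, sprintf("reference_%s.fasta", rg)))
}

writeLines(lineage_rows, file.path(out_dir, "taxonomy.tsv"))
design <- do.call(rbind, design_rows)
write.table(design, "results/sim_design.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("design table: results/sim_design.tsv; reads under ", out_dir)
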