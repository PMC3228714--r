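#!/usr/bin/env Rscript
# Cross-sample taxonomic comparison from the per-sample assignments
# written by analysis/02_run_pipeline.R: genus-by-sample abundance matrix
# normalized to 100000 reads, per-genus prevalence, and the per-sample
# dominant-genus flag (share >= 75% of assigned reads). Also checks the
# assignments against the simulation truth tables.

suppressPackageStartupMessages(library(uridiv))

sim_dir <- "scratch/sim"
pipe_dir <- "scratch/pipeline"
if (!dir.exists(pipe_dir)) stop("run analysis/02_run_pipeline.R first")
dir.create("results", showWarnings = FALSE)

tree <- read_taxonomy(file.path(sim_dir, "taxonomy.tsv"))
samples <- sprintf("F%d", 1:8)
regions <- c("V1V2", "V6")

assignments <- list()
agree <- list()
for (rg in regions) {
  for (sid in samples) {
    a <- read.delim(file.path(pipe_dir, sprintf("%s_%s_assign.tsv", sid, rg)),
                    stringsAsFactors = FALSE)
    assignments[[sprintf("%s_%s", sid, rg)]] <- a
    truth <- read.delim(file.path(sim_dir,
                                  sprintf("%s_%s_truth.tsv", sid, rg)),
                        stringsAsFactors = FALSE)
    # genus-level agreement with truth on assigned, non-contaminant reads
    tr <- truth[match(a$read_id, truth$read_id), ]
    keep <- !a$node %in% c("NotAssigned", "NoHits") & !tr$contaminant
    genus_of <- function(nodes) vapply(nodes, function(nd) {
      anc <- uridiv:::rank_ancestor(tree, nd, "genus")
      if (is.na(anc)) nd else anc
    }, character(1))
    truth_sp <- sprintf("%s_sp%s", rg, sub(".*_T", "", tr$template_id))
    ok <- genus_of(a$node[keep]) == genus_of(truth_sp[keep])
    agree[[sprintf("%s_%s", sid, rg)]] <- data.frame(
      sample = sid, region = rg, reads_checked = sum(keep),
      genus_agreement = mean(ok), stringsAsFactors = FALSE)
  }
}

cmp <- compare_samples(assignments, tree)
gm <- data.frame(genus = rownames(cmp$genus_matrix),
                 round(cmp$genus_matrix, 1), check.names = FALSE)
write.table(gm, "results/genus_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
prev <- data.frame(genus = names(cmp$prevalence),
                   samples_present = as.integer(cmp$prevalence),
                   of = cmp$n_samples)
write.table(prev, "results/genus_prevalence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp$dominant, "results/dominance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
agree_tab <- do.call(rbind, agree)
rownames(agree_tab) <- NULL
write.table(agree_tab, "results/genus_agreement.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("dominant-genus flags:")
print(cmp$dominant)
message("mean genus-level agreement with truth: ",
        round(mean(agree_tab$genus_agreement), 4))
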