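#' Pipeline options
#'
#' Tunable parameters of [run_sample()], with the pipeline's defaults:
#' length cutoffs 218 (V1V2) / 235 (V6), denoise radius 3 differences
#' with homopolymer discount, precluster radius 2, decontamination by
#' complete linkage at 1% with the 50% majority rule, average-linkage
#' OTUs at 3/6/10%, LCA taxonomy with bit score 100, top-percent 10,
#' minimum support 5, normalization to 100000 reads.
#'
#' @param min_len trimmed-length cutoff; `NULL` uses the region default.
#' @param denoise_max_diffs,hp_discount denoiser radius and homopolymer
#'   discount flag.
#' @param precluster_max_diffs precluster radius.
#' @param decontam_cutoff,decontam_threshold contamination filter
#'   clustering cutoff and control-share threshold.
#' @param linkage OTU clustering linkage.
#' @param cutoffs OTU distance cutoffs.
#' @param weighted weight average linkage by read counts?
#' @param subsample_size,subsample_reps normalized-Shannon subsample size
#'   (`NULL` = full depth) and replicate count.
#' @param min_score,top_percent,min_support LCA assignment parameters.
#' @param normalize_target common read total for cross-sample summaries.
#' @return a named list of options.
#' @export
pipeline_options <- function(min_len = NULL,
                             denoise_max_diffs = 3, hp_discount = TRUE,
                             precluster_max_diffs = 2,
                             decontam_cutoff = 0.01,
                             decontam_threshold = 0.5,
                             linkage = "average",
                             cutoffs = c(0.03, 0.06, 0.10),
                             weighted = TRUE,
                             subsample_size = NULL, subsample_reps = 100L,
                             min_score = 100, top_percent = 0.10,
                             min_support = 5L, normalize_target = 100000) {
  list(min_len = min_len, denoise_max_diffs = denoise_max_diffs,
       hp_discount = hp_discount,
       precluster_max_diffs = precluster_max_diffs,
       decontam_cutoff = decontam_cutoff,
       decontam_threshold = decontam_threshold,
       linkage = linkage, cutoffs = cutoffs, weighted = weighted,
       subsample_size = subsample_size, subsample_reps = subsample_reps,
       min_score = min_score, top_percent = top_percent,
       min_support = min_support, normalize_target = normalize_target)
}

#' Run the full pipeline for one sample and region
#'
#' Stages, in order: primer split, primer trim + length filter,
#' dereplication, denoising, contamination filtering against the
#' region-matched negative control, preclustering, pairwise distances,
#' hierarchical OTU clustering, diversity estimation and (optionally)
#' LCA taxonomy. Per-stage read counts are logged to `message()` and
#' returned.
#'
#' @param reads sequence records of the sample (pre-split, any region).
#' @param control_reads sequence records of the sample's negative
#'   extraction control, or `NULL` to skip the contamination filter.
#' @param region amplicon region to process.
#' @param primers a [primer_table()].
#' @param sample_id sample label for the summary row.
#' @param opts a [pipeline_options()] list.
#' @param taxonomy optional list: either `list(hits =, tree =)` with a
#'   per-representative hit list for the *cleaned* dereplicated set, or
#'   `list(community =, tree =)` to score hits with [toy_hit_table()].
#' @param seed RNG seed (drives subsampling only; the pipeline itself is
#'   deterministic).
#' @return a list with `counters`, `cleaned` (derep set), `preclustered`,
#'   `partitions`, `diversity`, `assignment` (or `NULL`),
#'   `decontam_report`, and `summary` (one-row `data.frame` shaped like
#'   the study's per-sample table).
#' @export
run_sample <- function(reads, control_reads = NULL, region = "V1V2",
                       primers = default_primers(), sample_id = "sample",
                       opts = pipeline_options(), taxonomy = NULL,
                       seed = 1L) {
  check_region(region)
  fwd <- primers[primers$orientation == "forward" &
                   primers$region == region, , drop = FALSE]
  if (nrow(fwd) != 1) stop("need exactly one forward primer for ", region)

  log_stage <- function(stage, n_in, n_out, unit = "reads")
    message(sprintf("[%s/%s] %-14s %6d -> %6d %s",
                    sample_id, region, stage, n_in, n_out, unit))

  total <- nrow(reads)
  buckets <- split_by_primer(reads, primers)
  regional <- buckets[[region]]
  if (is.null(regional)) regional <- reads[0, , drop = FALSE]
  log_stage("split", total, nrow(regional))

  trimmed <- trim_and_filter(regional, fwd, opts$min_len)
  log_stage("length_cutoff", nrow(regional), nrow(trimmed))

  dereps <- dereplicate(trimmed)
  denoised <- denoise(dereps, opts$denoise_max_diffs, opts$hp_discount)
  log_stage("denoise", derep_reads(dereps), derep_reads(denoised))

  control_derep <- NULL
  if (!is.null(control_reads) && nrow(control_reads) > 0) {
    cb <- split_by_primer(control_reads, primers)[[region]]
    if (!is.null(cb) && nrow(cb) > 0) {
      ct <- trim_and_filter(cb, fwd, opts$min_len)
      if (nrow(ct) > 0)
        control_derep <- denoise(dereplicate(ct), opts$denoise_max_diffs,
                                 opts$hp_discount)
    }
  }
  if (!is.null(control_derep) && derep_reads(denoised) > 0) {
    dec <- decontaminate(denoised, control_derep,
                         cutoff = opts$decontam_cutoff,
                         threshold = opts$decontam_threshold)
  } else {
    dec <- list(kept = denoised,
                report = data.frame(id = character(0), cluster = integer(0),
                                    control_fraction = numeric(0)),
                skipped = TRUE)
  }
  cleaned <- dec$kept
  log_stage("decontam", derep_reads(denoised), derep_reads(cleaned))

  counters <- pipeline_counters(total, nrow(regional), nrow(trimmed),
                                derep_reads(denoised), derep_reads(cleaned))

  pre <- precluster(cleaned, opts$precluster_max_diffs)
  log_stage("precluster", unique_otus(cleaned), unique_otus(pre),
            unit = "unique seqs")

  partitions <- NULL
  div <- NULL
  if (unique_otus(pre) > 0) {
    d <- pairwise_distance_matrix(pre)
    partitions <- hier_cluster(d, pre$count, linkage = opts$linkage,
                               cutoffs = opts$cutoffs,
                               weighted = opts$weighted)
    p3 <- partitions[[format_cutoff(min(opts$cutoffs))]]
    div <- diversity_estimate(p3, subsample_size = opts$subsample_size,
                              subsample_reps = opts$subsample_reps,
                              seed = stream_seed(seed, "shannon", sample_id,
                                                 region))
  }

  assignment <- NULL
  tax_counts <- c(phyla = NA_integer_, genera = NA_integer_)
  if (!is.null(taxonomy) && unique_otus(cleaned) > 0) {
    hits <- taxonomy$hits
    if (is.null(hits)) hits <- toy_hit_table(cleaned, taxonomy$community)
    read_hits <- replicate_hits(hits, cleaned)
    assignment <- lca_assign(read_hits, taxonomy$tree,
                             min_score = opts$min_score,
                             top_percent = opts$top_percent,
                             read_ids = unlist(cleaned$members))
    assignment <- apply_min_support(assignment, opts$min_support)
    summ <- normalize_and_summarize(setNames(list(assignment), sample_id),
                                    taxonomy$tree,
                                    target = opts$normalize_target)
    tax_counts <- c(phyla = summ$counts$phyla[1],
                    genera = summ$counts$genera[1])
  }

  cuts <- sort(opts$cutoffs)
  otu_n <- function(k) {
    if (is.null(partitions) || length(cuts) < k) return(NA_integer_)
    partitions[[format_cutoff(cuts[k])]]$n_otus
  }
  summary <- data.frame(
    sample = sample_id, region = region,
    total_reads = nrow(regional),
    length_cutoff = nrow(trimmed),
    denoised = derep_reads(denoised),
    cleaned = derep_reads(cleaned),
    unique_otus = unique_otus(cleaned),
    otus_3 = otu_n(1), otus_6 = otu_n(2),
    phyla = tax_counts[["phyla"]], genera = tax_counts[["genera"]],
    chao1 = if (is.null(div)) NA_real_ else div$chao1$chao1,
    chao1_lci95 = if (is.null(div)) NA_real_ else div$chao1$lci95,
    chao1_hci95 = if (is.null(div)) NA_real_ else div$chao1$hci95,
    shannon = if (is.null(div)) NA_real_ else div$shannon,
    shannon_normalized = if (is.null(div)) NA_real_
                         else div$shannon_normalized,
    stringsAsFactors = FALSE)

  list(counters = counters, cleaned = cleaned, preclustered = pre,
       partitions = partitions, diversity = div, assignment = assignment,
       decontam_report = dec$report, decontam_skipped = dec$skipped,
       summary = summary)
}

#' Run one sample from a declarative configuration file
#'
#' The configuration is a YAML key-value file whose keys mirror the
#' [run_sample()] arguments and [pipeline_options()] names:
#' `reads` (FASTA path, required), `control` (FASTA path, optional),
#' `region`, `sample_id`, `seed`, `taxonomy_hits` (BLAST-tabular path) +
#' `taxonomy_lineages` (lineage table path), and any pipeline option
#' (e.g. `cutoffs`, `min_support`). Values given in `overrides` take
#' precedence over the file, mirroring flags overriding a config file.
#' The effective configuration is attached to the result as attribute
#' `"config"` for provenance.
#'
#' @param path path to the YAML configuration file.
#' @param overrides named list of values overriding the file.
#' @return the [run_sample()] result list.
#' @export
run_sample_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$reads)) stop("config must name a 'reads' FASTA")
  region <- cfg$region %||% "V1V2"
  sample_id <- cfg$sample_id %||% "sample"
  reads <- read_fasta(cfg$reads, sample = sample_id)
  control <- if (!is.null(cfg$control))
    read_fasta(cfg$control, sample = "control") else NULL
  opt_names <- names(formals(pipeline_options))
  opts <- do.call(pipeline_options, cfg[intersect(names(cfg), opt_names)])
  taxonomy <- NULL
  if (!is.null(cfg$taxonomy_hits) && !is.null(cfg$taxonomy_lineages)) {
    taxonomy <- list(hits = read_hit_table(cfg$taxonomy_hits),
                     tree = read_taxonomy(cfg$taxonomy_lineages))
  }
  res <- run_sample(reads, control_reads = control, region = region,
                    sample_id = sample_id, opts = opts,
                    taxonomy = taxonomy,
                    seed = as.integer(cfg$seed %||% 1L))
  attr(res, "config") <- cfg
  res
}

#' Cross-sample comparison of normalized genus profiles
#'
#' Builds the genus-by-sample normalized abundance matrix, per-genus
#' prevalence (how many samples carry the genus), and a per-sample
#' dominant-genus flag (set when one genus holds at least
#' `dominance` of the sample's assigned reads).
#'
#' @param assignments named list of assignment `data.frame`s per sample.
#' @param tree the `taxonomy_tree`.
#' @param target normalization read total.
#' @param dominance dominant-genus share threshold (default 0.75).
#' @return a list with `genus_matrix`, `prevalence` (named integer
#'   vector), `n_samples`, and `dominant` (`data.frame` of per-sample
#'   top genus, share and flag).
#' @export
compare_samples <- function(assignments, tree, target = 100000,
                            dominance = 0.75) {
  if (length(assignments) < 2) stop("need at least 2 samples to compare")
  summ <- normalize_and_summarize(assignments, tree, target = target)
  g <- summ$tables$genus
  prevalence <- apply(g > 0, 1, sum)
  dominant <- data.frame(
    sample = colnames(g),
    top_genus = apply(g, 2, function(col)
      if (all(col == 0)) NA_character_ else rownames(g)[which.max(col)]),
    share = apply(g, 2, function(col)
      if (sum(col) == 0) NA_real_ else max(col) / sum(col)),
    row.names = NULL, stringsAsFactors = FALSE)
  dominant$dominant <- !is.na(dominant$share) & dominant$share >= dominance
  list(genus_matrix = g, prevalence = prevalence,
       n_samples = length(assignments), dominant = dominant)
}

#' Write per-sample summary rows as a tab-separated table
#'
#' @param summaries a `data.frame` of [run_sample()] summary rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_summary <- function(summaries, path) {
  write.table(summaries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
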