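#' Pyrosequencing-style error model
#'
#' Two error modes: uniform per-base substitutions, and insertion/deletion
#' errors at homopolymer runs (the characteristic pyrosequencing error
#' mode). Indels are applied per homopolymer run of length >= 2: with
#' probability `hp_indel_rate` the run is lengthened or shortened by up to
#' `max_indel` bases.
#'
#' @param sub_rate per-base substitution probability.
#' @param hp_indel_rate per-homopolymer-run indel probability.
#' @param max_indel maximum run-length change per indel event.
#' @return an `error_model` list.
#' @export
error_model <- function(sub_rate = 0, hp_indel_rate = 0, max_indel = 1L) {
  if (sub_rate < 0 || sub_rate > 1 || hp_indel_rate < 0 || hp_indel_rate > 1)
    stop("error rates must lie in [0, 1]")
  if (max_indel < 1) stop("max_indel must be >= 1")
  structure(list(sub_rate = sub_rate, hp_indel_rate = hp_indel_rate,
                 max_indel = as.integer(max_indel)),
            class = "error_model")
}

#' Community model: templates with abundances
#'
#' @param templates named character vector of template sequences
#'   (names are template ids; sequences must be pairwise distinct).
#' @param abundances probability vector over templates (sums to 1).
#' @param taxa optional named character vector mapping template ids to
#'   taxonomy node ids.
#' @param region amplicon region the community is observed through.
#' @return a `community_model` list.
#' @export
community_model <- function(templates, abundances = NULL, taxa = NULL,
                            region = "unknown") {
  if (is.null(names(templates)))
    names(templates) <- sprintf("T%03d", seq_along(templates))
  if (anyDuplicated(templates)) stop("template sequences must be distinct")
  if (is.null(abundances))
    abundances <- rep(1 / length(templates), length(templates))
  if (length(abundances) != length(templates))
    stop("abundances length must match templates")
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  check_region(region)
  structure(list(templates = templates, abundances = abundances,
                 taxa = taxa, region = region),
            class = "community_model")
}

#' Generate mutually divergent template sequences
#'
#' Templates emulate co-amplified 16S gene variants: every template is a
#' point-mutation variant of one shared ancestral backbone, so any pair
#' is globally alignable (as real same-region amplicons are) while still
#' diverged. Each template substitutes a `divergence` fraction of
#' backbone positions at random; candidates are rejected until all
#' pairwise alignment distances (package convention, see
#' [seq_distance()]) are at least `min_divergence`. Two templates mutated
#' at rate r sit about 2r apart, so the default `divergence =
#' min_divergence` leaves comfortable slack above the floor.
#'
#' @param n number of templates.
#' @param length template length in bases.
#' @param min_divergence minimum pairwise distance, in (0, 1).
#' @param seed RNG seed.
#' @param divergence per-template substituted fraction of the backbone.
#' @param backbone ancestral sequence to mutate; `NULL` draws a random
#'   one. Pass the `"backbone"` attribute of an earlier template set to
#'   generate further sequences divergent from it (e.g. a contamination
#'   source sharing the same gene).
#' @param exclude character vector of sequences the new templates must
#'   also be at least `min_divergence` away from.
#' @param max_tries candidate draws allowed per accepted template.
#' @return named character vector of `n` sequences, with the backbone as
#'   attribute `"backbone"`.
#' @export
generate_templates <- function(n, length, min_divergence, seed,
                               divergence = min_divergence,
                               backbone = NULL, exclude = character(0),
                               max_tries = 200L) {
  if (n < 1) stop("n must be >= 1")
  if (min_divergence <= 0 || min_divergence >= 1)
    stop("min_divergence must lie in (0, 1)")
  if (divergence <= 0 || divergence >= 1)
    stop("divergence must lie in (0, 1)")
  with_seed(stream_seed(seed, "templates"), {
    if (is.null(backbone)) backbone <- random_dna(length)
    bases <- c("A", "C", "G", "T")
    bb <- strsplit(backbone, "")[[1]]
    nsub <- max(1L, round(divergence * base::length(bb)))
    out <- character(0)
    against <- as.character(exclude)
    while (base::length(out) < n) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- bb
        pos <- sample.int(base::length(bb), nsub)
        for (p in pos) cand[p] <- sample(setdiff(bases, cand[p]), 1)
        cand <- paste0(cand, collapse = "")
        d <- vapply(against, function(s) nw_dist_cpp(cand, s), numeric(1))
        if (all(d >= min_divergence)) {
          out <- c(out, cand)
          against <- c(against, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place template ", base::length(out) + 1,
             " after ", max_tries, " tries; relax n/length/min_divergence")
    }
    structure(setNames(out, sprintf("T%03d", seq_len(n))),
              backbone = backbone)
  })
}

#' Geometric-series community abundances
#'
#' Rank-abundance profile p_i proportional to `shape^(i-1)`, normalized.
#' `shape = 1` is the uniform community; `shape` near 0.25 gives a
#' dominant first template holding at least 75% of the reads.
#'
#' @param n number of templates.
#' @param shape geometric ratio, > 0.
#' @param seed accepted for interface symmetry; the profile is
#'   deterministic.
#' @return probability vector of length `n`.
#' @export
sample_abundances <- function(n, shape, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (shape <= 0) stop("shape must be > 0")
  p <- shape^(seq_len(n) - 1)
  p / sum(p)
}

# Apply the error model to one sequence; returns list(seq, errors).
#' @noRd
mutate_sequence <- function(seq, error) {
  chars <- strsplit(seq, "")[[1]]
  nerr <- 0L
  if (error$sub_rate > 0) {
    hit <- which(runif(length(chars)) < error$sub_rate)
    for (p in hit) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    nerr <- nerr + length(hit)
  }
  if (error$hp_indel_rate > 0) {
    r <- rle(chars)
    lens <- r$lengths
    for (k in which(lens >= 2)) {
      if (runif(1) < error$hp_indel_rate) {
        mag <- if (error$max_indel == 1L) 1L else sample.int(error$max_indel, 1)
        delta <- sample(c(-1L, 1L), 1) * mag
        lens[k] <- max(lens[k] + delta, 0L)
        if (lens[k] == r$lengths[k]) lens[k] <- r$lengths[k] + mag
        nerr <- nerr + 1L
      }
    }
    chars <- rep(r$values, lens)
  }
  list(seq = paste0(chars, collapse = ""), errors = nerr)
}

# Resolve IUPAC ambiguity codes to concrete bases (one random choice per
# ambiguous position), as in a mixed-base primer batch.
#' @noRd
resolve_iupac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  amb <- which(!chars %in% c("A", "C", "G", "T"))
  for (p in amb) {
    chars[p] <- sample(strsplit(IUPAC_SETS[[chars[p]]], "")[[1]], 1)
  }
  paste0(chars, collapse = "")
}

#' Simulate amplicon reads from a community
#'
#' Each read is the composite primer (ambiguity codes resolved once per
#' call, emulating one dominant primer species in the batch) followed by
#' a template drawn by abundance, with the error model applied across the
#' whole assembled read -- so with nonzero rates reads can lose their
#' exact primer match and be discarded at the split stage, as on the real
#' platform. Fixing the seed fixes every emitted byte.
#'
#' @param community a [community_model()].
#' @param n_reads number of reads to draw.
#' @param error an [error_model()].
#' @param primer one row of a [primer_table()] (forward orientation).
#' @param seed RNG seed.
#' @param sample sample label for the emitted records.
#' @param id_prefix prefix for read ids.
#' @param contaminant logical flag recorded in the truth table.
#' @return `list(reads = sequence records, truth = data.frame(read_id,
#'   template_id, contaminant, errors))`.
#' @export
generate_reads <- function(community, n_reads, error = error_model(),
                           primer, seed, sample = "sample",
                           id_prefix = sample, contaminant = FALSE) {
  if (n_reads < 0) stop("n_reads must be >= 0")
  stopifnot(inherits(community, "community_model"))
  composite <- paste0(primer$adapter, primer$target)
  with_seed(stream_seed(seed, "reads", id_prefix), {
    idx <- if (n_reads > 0)
      sample.int(length(community$templates), n_reads, replace = TRUE,
                 prob = community$abundances) else integer(0)
    concrete_primer <- resolve_iupac(composite)
    seqs <- character(n_reads)
    errs <- integer(n_reads)
    for (r in seq_len(n_reads)) {
      assembled <- paste0(concrete_primer,
                          community$templates[[idx[r]]])
      m <- mutate_sequence(assembled, error)
      seqs[r] <- m$seq
      errs[r] <- m$errors
    }
    ids <- sprintf("%s_r%05d", id_prefix, seq_len(n_reads))
    reads <- sequence_records(ids, seqs, sample = sample,
                              region = community$region)
    truth <- data.frame(read_id = ids,
                        template_id = names(community$templates)[idx],
                        contaminant = rep(contaminant, n_reads),
                        errors = errs, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Spike reagent contamination into a sample
#'
#' Adds contaminant reads drawn from a control community so that they form
#' `fraction` of the augmented read set (nearest integer), and emits an
#' independent control read set from the same community, emulating a
#' negative extraction control sequenced alongside the sample.
#'
#' @param sample_reads sequence records of the sample.
#' @param control_community a [community_model()] of the contamination
#'   source.
#' @param fraction contaminant share of the augmented sample, in [0, 1).
#' @param error an [error_model()] for the spiked and control reads.
#' @param primer forward primer row used for the region.
#' @param seed RNG seed.
#' @param n_control_reads size of the emitted control read set.
#' @return `list(sample = augmented records, control = control records,
#'   truth = truth rows for the added contaminant reads)`.
#' @export
spike_contamination <- function(sample_reads, control_community, fraction,
                                error = error_model(), primer, seed,
                                n_control_reads = 500L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  n_s <- nrow(sample_reads)
  n_c <- round(n_s * fraction / (1 - fraction))
  sample_lab <- if (n_s > 0) sample_reads$sample[1] else "sample"
  spike <- generate_reads(control_community, n_c, error, primer,
                          seed = stream_seed(seed, "spike", sample_lab),
                          sample = sample_lab,
                          id_prefix = paste0(sample_lab, "_cont"),
                          contaminant = TRUE)
  control <- generate_reads(control_community, n_control_reads, error, primer,
                            seed = stream_seed(seed, "control", sample_lab),
                            sample = paste0(sample_lab, "_control"),
                            id_prefix = paste0(sample_lab, "_ctrl"),
                            contaminant = TRUE)
  list(sample = rbind(sample_reads, spike$reads),
       control = control$reads,
       truth = spike$truth)
}

#' Write a simulation truth table
#'
#' @param truth a truth `data.frame` from [generate_reads()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
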