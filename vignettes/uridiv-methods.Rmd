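---
title: "Methods: amplicon diversity estimation for low-biomass urine samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon diversity estimation for low-biomass urine samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uridiv)
```

## The problem

Urine from healthy people is culture-negative under standard clinical
criteria, yet carries bacterial 16S rDNA from fastidious and anaerobic
taxa that evade cultivation. Characterizing that community from amplicon
pyrosequencing reads is a low-biomass problem: read numbers are modest,
homopolymer-run indel errors inflate apparent diversity, and reagent
contamination can rival the genuine signal. `uridiv` implements the full
analysis chain for such data -- two hypervariable regions (V1V2 and V6)
amplified with composite adapter+target primers, processed per sample
against a negative extraction control -- together with a simulator that
generates communities with known ground truth, so every stage of the
chain is testable without any sequencing data.

## Pipeline stages and their parameters

`run_sample()` executes, in order:

1. **Region splitting** (`split_by_primer`). A read is assigned to a
   region only if its 5' end matches the region's composite primer
   exactly; IUPAC ambiguity codes in the primer match their base sets,
   never the reverse. Exact matching deliberately discards reads with a
   damaged primer, as the upstream platform tooling does.
2. **Trimming and length filtering** (`trim_and_filter`). The primer is
   removed and reads shorter than the region minimum are dropped --
   218 nt for V1V2 and 235 nt for V6, inclusive: the cutoffs are read as
   minimum acceptable lengths, so a 218/235-nt read survives. The cutoff
   is applied to the trimmed read; the choice of trimming first is
   recorded in the output metadata.
3. **Dereplication** (`dereplicate`). Identical reads collapse to one
   entry carrying a read count; counts are the abundance weights for
   everything downstream.
4. **Denoising** (`denoise`). A sequence-space treatment of the
   platform's error structure: entries sorted by (count desc, length
   desc, sequence) are greedily absorbed into the first earlier, more
   abundant seed within `max_diffs` (default 3) alignment differences.
   With `hp_discount` (default on), an indel column adjacent to a
   homopolymer run of length >= 2 costs half a difference, widening the
   radius specifically for the platform's characteristic indel mode.
   This is an abundance-aware merger operating on sequences; it is not a
   flowgram-likelihood model, and it is documented and tested as such
   (against simulation truth: error-free reads from templates more
   divergent than the radius are never merged across templates).
5. **Contamination filtering** (`decontaminate`). The sample and its
   region-matched negative control are pooled and complete-linkage
   clustered at 1% genetic difference. Control entries are first
   weighted so the weighted control total equals the sample total
   exactly (the weighting is otherwise purposeless, which is why the
   majority rule is computed on weights; `count_mode = "entries"`
   preserves the alternative reading). Sample sequences in clusters
   whose control share reaches 50% -- boundary inclusive, "50% or more"
   -- are removed. With an empty control the filter is skipped with a
   warning. The filter is idempotent: re-running it removes nothing
   further, because removing sample reads only lowers the control
   multiplier.
6. **Preclustering** (`precluster`). The single-pass abundance-ranked
   merger again, radius 2 differences, no discount: short rare variants
   join longer abundant seeds, absorbing residual noise before OTU
   formation. Merging is single-pass against retained *seeds*: a chain
   A-B-C where C is within radius of B but not of A leaves C standing.
7. **Distances** (`pairwise_distance_matrix`). Needleman-Wunsch global
   alignment with free terminal gaps (semi-global), match +1, mismatch
   -1, gap -2 per column; distance = (mismatches + internal gap
   columns) / compared columns, where compared columns exclude terminal
   gap runs. Each internal gap *column* counts as one difference (the
   alternative, one per gap run, is not used). Scoring parameters are
   explicit, overridable guesses in the spirit of the standard tools;
   only the counting convention is fixed by design.
8. **OTU clustering** (`hier_cluster`). Agglomerative clustering with
   single, complete, or read-count-weighted average linkage (weighted is
   the default, matching tools that operate on replicated reads;
   `weighted = FALSE` gives the per-unique-sequence alternative).
   A partition emitted at cutoff c contains every merge with criterion
   <= c; merging stops at the first merge exceeding c. Ties are broken
   toward the lowest pair of smallest member indices, so runs are fully
   deterministic. Default cutoffs 3%, 6%, 10% (species, genus, family
   proxies).
9. **Diversity** (`chao1`, `shannon`, `normalized_shannon`,
   `rarefaction_curve`) and **taxonomy** (`lca_assign` and friends),
   described below.

## Numerical conventions worth knowing

**Distance symmetry.** Co-optimal alignments can carry different
difference counts, and a deterministic traceback may pick different
representatives for (a, b) and (b, a). Distances are therefore always
computed on a canonical ordering of the pair, making `d(a,b) == d(b,a)`
exact, as the symmetry invariant requires. The chosen alignment is
always optimal for the pair.

**Free end gaps and unrelated sequences.** With free terminal gaps, two
*unrelated* random sequences can receive a small distance (a short
perfect overlap outscores the full-length alignment). Real same-region
16S amplicons are globally similar, so this situation does not arise in
the data the convention was designed for -- but it shapes the simulator:
templates are generated as point-mutation variants of one shared
backbone (like real gene variants), not as independent random strings.

**Chao1.** The bias-corrected form `Sobs + n1(n1-1)/(2(n2+1))` is the
default because it is defined when no doubletons exist; the classic form
is available behind a flag. The 95% interval is the log-normal
construction on the variance of the unseen-species estimate, with the
three-case variance (n1>0 & n2>0; n1>0 & n2=0; n1=0). With no singletons
the interval collapses to (Sobs, Sobs). The construction yields the
asymmetric intervals characteristic of reported Chao1 CIs, with the
lower bound close to the estimate.

**Shannon.** Natural logarithm; the magnitudes of the reported indices
(~4 for ~500 OTUs) are consistent with ln, not log2 or log10. The
normalized variant draws `reps` (default 100) subsamples without
replacement at a common size -- the smallest cleaned read count in the
sample group -- and averages the resulting indices; each replicate uses
its own derived RNG stream, so the estimate is reproducible and
independent of evaluation order, and at full depth it equals the plain
index exactly.

**Rarefaction.** The analytic hypergeometric expectation
`E[S(m)] = Sobs - sum_i C(N - c_i, m) / C(N, m)`, evaluated in log space;
it equals the exhaustive mean over all subsamples (tested by full
enumeration at small n) without Monte-Carlo noise.

**LCA taxonomy.** Hits below 100 bits are dropped; of the rest, hits
within 10% of the best bit score are retained and the read is placed on
the lowest common ancestor of their taxa. The 10% window is the
conventional default of LCA assignment tools; it is exposed
(`top_percent`), and `top_percent = 1` reproduces the
use-all-kept-hits reading. Taxa assigned fewer than 5 reads are not
reported; their reads move to the NotAssigned bucket (not to the parent
node). Counts normalize to 100 000 reads per sample for comparison, and
reads are bucketed so that assigned + NotAssigned + NoHits always equals
the read total.

## What the simulator emulates -- and what it does not

`generate_templates` produces co-amplifiable gene variants over one
backbone with a guaranteed pairwise distance floor; `sample_abundances`
is a one-parameter geometric rank-abundance profile (shape 0.2-0.25
reproduces the dominated communities seen in real urine samples, where
one genus holds >= 75% of reads; shape 1 is uniform);
`generate_reads` assembles primer + template and applies uniform
substitutions plus per-homopolymer-run indels (runs >= 2, +/- up to
`max_indel` bases), the platform's characteristic error mode;
`spike_contamination` adds reagent reads shared between the sample and
an independently emitted negative control. A single seed fixes every
emitted byte.

Not emulated: chimeras, quality scores, flowgrams, position-dependent
error rates, and length variation between gene variants (templates of a
region share one length; length variation in the pipeline arises only
through indels). Passing tests on these data therefore demonstrate the
correctness of the pipeline's logic and estimators under the stated
error model, not robustness to every artifact of real amplicon data.

## Benchmark conditions

The test suite runs scaled-down versions of every benchmark so the whole
suite stays in the minutes range; sizes are stated with each test. Two
deserve explanation:

* **Template recovery** uses 50 templates at >= 5% divergence with
  near-even abundances (shape 0.98) and 2000 error-free reads, so every
  template is expected well above doubleton depth and the correct
  outcome is exactly 50 OTUs at 3% with a degenerate Chao1 interval.
* **Chao1 interval coverage** uses a 60-template near-even community
  (shape 0.98) sampled at depth 200, conditioned on n1 > 0. Coverage is
  a property of the interval construction, which presupposes small
  estimator bias and genuinely incomplete sampling: a 75%-dominated
  community would test Chao1's known downward bias instead, and at
  depths where sampling is nearly complete the log-normal lower bound
  sits just above Sobs = true richness, so the interval misses by
  construction. At depth 200 about 3-4 templates remain unseen per
  replicate and the nominal 95% interval covers ~94% of replicates;
  the acceptance requirement is >= 80%.

## Known limitations

* The denoiser is a documented stand-in for flowgram-based denoising;
  on real data it will under-correct errors that perturb more than
  `max_diffs` positions and, like any abundance-greedy merger, can
  absorb a genuine low-abundance variant lying within the radius of a
  dominant sequence.
* Average-linkage criteria are updated incrementally (Lance-Williams);
  exact agreement with the from-scratch definition is guaranteed
  mathematically and verified against an exhaustive reference
  implementation, but merge order between criteria differing only at
  floating-point resolution is decided by the deterministic tie-break.
* The toy hit generator scores full-length global alignments with a
  blastn-like bit score (+2 match / -3 difference); it exists so the
  taxonomy stage is testable without an external search tool, and real
  BLAST tabular hit tables are accepted unchanged.
* `hier_cluster` is quadratic in memory and cubic in time; it is meant
  for the post-precluster scale (hundreds of unique sequences), not for
  raw read sets.
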