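# uridiv

Diversity analysis of 16S rDNA amplicon reads from culture-negative,
low-biomass urine specimens.

Urine that is sterile by clinical culture criteria still yields bacterial
16S rDNA when amplified and sequenced. Quantifying that community from
pyrosequencing-style amplicon reads poses three problems at once:
homopolymer-run indel errors inflate the apparent number of sequence
variants, reagent contamination can rival the genuine signal at low
biomass, and samples of unequal depth are not directly comparable.
`uridiv` implements the complete analysis chain for this setting, for
microbiome researchers working with region-amplified (V1V2 / V6) reads
and negative extraction controls:

* primer-exact region splitting, trimming, inclusive length cutoffs
  (218 nt V1V2 / 235 nt V6), dereplication;
* an abundance-ranked sequence-space denoiser with a homopolymer
  discount;
* negative-control contamination filtering: sample + control pooled,
  complete-linkage clustered at 1% difference with the control weighted
  to equal representation, and sample sequences removed from clusters
  with >= 50% control share;
* Needleman-Wunsch pairwise distances with free terminal gaps, counting
  d = (mismatches + internal gap columns) / compared columns;
* hierarchical OTU clustering (read-count-weighted average linkage by
  default) with partitions at 3% / 6% / 10%;
* Chao1 richness `S_chao1 = S_obs + n1(n1-1) / (2(n2+1))` with the
  log-normal 95% CI, Shannon index `H' = -sum p_i ln p_i`, a
  100-replicate subsample-normalized Shannon index, and analytic
  rarefaction `E[S(m)] = S_obs - sum_i C(N-c_i, m)/C(N, m)`;
* lowest-common-ancestor taxonomy from BLAST-tabular hit tables
  (E <= 1e-5, top 25 hits, bit score >= 100, 10% top-score window,
  minimum support 5, normalization to 100 000 reads);
* a ground-truthed simulator (template communities over a shared gene
  backbone, geometric abundances, substitution + homopolymer-indel
  errors, contamination spikes) that makes every stage testable.

## Worked example

Simulate a dominated 8-species community read set with realistic error
rates and run the full per-sample pipeline:

```r
library(uridiv)

primer    <- default_primers()[1, ]                     # V1V2 forward
templates <- generate_templates(8, 280, 0.05, seed = 11)
community <- community_model(templates, sample_abundances(8, 0.3),
                             region = "V1V2")
sim <- generate_reads(community, 1000,
                      error_model(sub_rate = 0.002, hp_indel_rate = 0.005),
                      primer, seed = 12, sample = "F1")

res <- run_sample(sim$reads, control_reads = NULL, region = "V1V2",
                  sample_id = "F1", seed = 1)
#> [F1/V1V2] split            1000 ->    897 reads
#> [F1/V1V2] length_cutoff     897 ->    897 reads
#> [F1/V1V2] denoise           897 ->    897 reads
#> [F1/V1V2] decontam          897 ->    897 reads
#> [F1/V1V2] precluster         11 ->     11 unique seqs

res$summary
#>  sample region total_reads length_cutoff denoised cleaned unique_otus otus_3
#>      F1   V1V2         897           897      897     897          11      7
#>  otus_6 phyla genera chao1 chao1_lci95 chao1_hci95   shannon shannon_normalized
#>       7    NA     NA     7           7           7 0.8699589          0.8699589
```

Reading the numbers: 103 of 1000 reads lost their exact primer match to
simulated sequencing error and were discarded at the split; denoising
collapsed 897 reads to 11 unique sequences; clustering at 3% found 7
OTUs -- the 8th template was simulated at abundance 1.5e-4 and was never
sampled. Chao1 equals the observed richness with a degenerate interval
(no singletons survive denoising here), and the Shannon index reflects
the dominated abundance profile. Rarefaction of the same partition:

```r
rarefaction_curve(res$partitions[["0.03"]]$cluster_counts,
                  c(10, 100, 500, 897))
#>  depth expected_otus
#>     10      2.614041
#>    100      4.629284
#>    500      6.360121
#>    897      7.000000
```

The full synthetic study (8 individuals x 2 regions with contamination
spikes and negative controls) lives in `analysis/01_simulate.R` through
`analysis/04_taxonomy_compare.R`; each driver writes its tables under
`results/`.

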