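# mastkit

Strain-level analysis of deep-sequenced amplicon marker genes
(metagenomic amplicon strain typing, MAST), for microbiome researchers
who want to resolve *within-species* population structure — which exact
haplotypes of a symbiont each host individual carries, which haplotypes
travel together, and whether shared haplotypes could be artifacts.

A **strain** is an exact full-length amplicon haplotype: two strains
differ by ≥ 1 nucleotide along the marker. The package implements the
full chain on that definition:

- **Strain calling** — merged reads are kept if their mean Phred score is
  ≥ 30, aligned ungapped (exact length), pooled into haplotype counts,
  and a haplotype becomes a strain iff its frequency exceeds 1%
  (strict `>`) in at least one sample. At 46,000× coverage that threshold
  is 460 reads.
- **Co-occurrence and clustering** — for strains A, B found in `b_A`,
  `b_B` hosts and jointly in `b_AB`, the score is the Sørensen–Dice form
  `S = 2 b_AB / (b_A + b_B)`; the strain×strain score matrix is clustered
  with an in-package Markov clustering (MCL) implementation
  (inflation sweep 1.2/2/4/6, analysis default I = 2.0), and clusters are
  profiled (sizes, clusters per host, within- vs between-cluster SNP
  distances with a Wilcoxon rank-sum test).
- **Randomization** — geography (shuffle hosts across locations),
  strain reassortment (richness-preserving, prevalence-weighted null),
  cross-marker association, and saturation (accumulation) curves; all
  chi-square statistics are calibrated against their own permutation
  distributions.
- **Evolution simulations** — Poisson substitution processes on the
  marker reference, uniform (PCR-artifact mode) or codon-position-
  weighted (purifying-selection mode), with cross-host sequence
  convergence counting.
- **Cryptic rescue** — re-search the unfiltered read pool for each called
  strain with single-read support, quantifying sub-threshold carriage.
- **Synthetic data** — a generator that plants clusters of closely
  related strains with shared abundance profiles and emits error-bearing
  FASTQ with known ground truth, so every stage is testable end to end.

## Worked example

Simulate a small planted study (12 bees from two locations, 5 strain
clusters of 4 strains each about 1 SNP apart, 2,000 reads per bee and
marker, 0.1% per-base error), then call, cluster and test:

```r
library(mastkit)

refs <- lapply(c("guaA", "gluS"), function(m)
  make_marker_reference(450, frame_offset = 0, seed = derive_seed(7, m),
                        marker_name = m))
truth <- make_truth(refs, n_bees = 12, locations = c(TX = 6, TN = 6),
                    n_clusters = 5, strains_per_cluster = 4,
                    two_cluster_fraction = 0, error_rate = 0.001,
                    coverage_mean = 2000, seed = 7)
sim <- simulate_reads(truth, read_sim_params(coverage_mean = 2000,
                                             error_rate = 0.001, seed = 8))
tab <- call_strains(sim$reads, refs)
summarize_strain_diversity(tab)
#>   marker n_strains mean_strains_per_bee sd_strains_per_bee mean_pairwise_snps
#> 1   guaA        20                    4                  0           14.97368
#> 2   gluS        20                    4                  0           14.56316
```

All 40 planted strains are recovered (20 per marker, 4 per bee — each bee
carries exactly one cluster here). Markov clustering of the co-occurrence
scores finds the planted clusters, and strains within a cluster are far
more similar than strains across clusters:

```r
cl <- mcl_cluster(build_cooccurrence_graph(tab, "guaA"), inflation = 2)
cl
#> <strain_clusters> 5 clusters over 20 strains (I = 2)
#>   sizes: 4 4 4 4 4

wb <- within_vs_between_snps(cl, tab, "guaA")
#> within-cluster mean SNPs 1.50 vs between 17.50 (Wilcoxon p = 8.21e-21)
```

Because clusters were planted independently of location, the geography
randomization finds nothing, and the saturation curve climbs to the full
strain count:

```r
meta <- truth$bee_assignments; names(meta) <- c("sample_id", "location")
location_shuffle_test(tab, meta, "guaA", n_reps = 999, seed = 9)
#> <permutation_result> location_shuffle (guaA)
#>   chi-square = 0.028 (df = 1), p = 1 (Bonferroni x1: 1)
#>   999 randomizations, seed 9

saturation_curve(tab, "guaA", n_combinations = 100, seed = 10)
#> <saturation_curve> guaA: 12 hosts, 4.0 strains at k=1, 20 at k=12
```

The in-silico evolution experiment asks whether identical haplotypes in
different hosts could arise by chance mutation alone. At full study scale
(144 hosts, 6 strains each, ~8 SNPs per strain on a 450 bp marker) every
generated sequence is unique:

```r
sets <- simulate_strain_set(refs[[1]], n_bees = 144, strains_per_bee = 6,
                            mean_snps = 8, seed = 11)
str(convergence_summary(sets))
#> List of 4
#>  $ n_sequences            : int 864
#>  $ n_distinct             : int 864
#>  $ n_convergent           : int 0
#>  $ n_within_bee_duplicates: int 0
```

A thin command-line wrapper over the same functions ships at
`inst/cli/mastkit.R` (subcommands `pipeline`, `simulate`, `call`,
`cluster`, `saturate`, `evolve`), and `run_pipeline()` orchestrates the
stages end to end from a single YAML config with checksum-based stage
skipping.

## Documentation

The methods vignette (`vignettes/mast-strain-typing.Rmd`) documents the
models and assumptions: the calling thresholds and their boundary
behavior, the MCL numerics, the design of each permutation null, the
codon-position substitution model, what the synthetic-data generator does
and does not emulate, and known limitations.
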