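---
title: "Strain typing from deep amplicon markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain typing from deep amplicon markers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastkit)
```

## The problem

Deep amplicon sequencing of species-specific protein-coding marker genes
(metagenomic amplicon strain typing, MAST) resolves within-species strain
structure in host-associated bacterial communities. A *strain* here is an
exact full-length amplicon haplotype: two strains differ by at least one
nucleotide along the marker. With tens of thousands of merged reads per
sample and marker, haplotypes down to ~1% within-sample frequency can be
called with confidence, and much rarer ones can at least be searched for.

`mastkit` implements the complete analysis chain on this definition:
quality filtering and ungapped alignment of merged reads, haplotype
counting and frequency thresholding, strain co-occurrence scoring and
Markov clustering, permutation nulls (geography, strain reassortment,
cross-species association), saturation curves, codon-position-aware
sequence-evolution simulations, and a single-read "cryptic strain"
rescue. A synthetic-data generator with planted ground truth makes every
stage testable end to end.

## Strain calling

Reads are retained when the **arithmetic mean of their Phred scores is at
least 30**; strictly lower means are discarded. The boundary case (mean
exactly 30) is retained, since only sub-30 means are excluded. Reads
containing ambiguous bases are discarded by default (`allow_n = FALSE`);
deep amplicon data lose essentially nothing to this rule and exact
haplotype identity is ill-defined with Ns.

Merged amplicons are fixed-length, so an indel anywhere forces a length
change. The gap-free alignment step is therefore implemented as an
**exact-length rule**: a read aligns iff its length equals the reference
length, and its base string is its haplotype. No mismatch cap is imposed
— divergent haplotypes are exactly what the method is after.

Identical haplotypes are pooled per (sample, marker) and frequencies are
computed against that sample's **retained, aligned** reads (the source
method does not state the denominator; retained-aligned is the
self-consistent choice since those are the reads that can support a
haplotype). A haplotype is promoted to the strain registry iff its
frequency **strictly exceeds** `freq_threshold` (default 0.01) in at
least one sample — at a mean coverage of 46,000 reads, 1% corresponds to
460 reads, so a 460-read variant is *not* called and a 461-read variant
is. Registry strains are reported in every sample with raw counts; the
`present` flag applies the same strict rule per sample. Strain ids are
assigned deterministically (per marker, by descending total read support,
ties broken lexicographically on the haplotype), so runs are reproducible
and diffable.

The **cryptic rescue** (`rescue_cryptic()`) re-searches the complete,
unfiltered read pool for each registry strain's exact haplotype and calls
it present in a sample on a single supporting read. It reports strict and
relaxed prevalences and their ratio; a large mean fold change indicates
that sub-threshold carriage is widespread (with the caveat that single
reads may be sequencing errors).

## Co-occurrence and Markov clustering

For strains A and B present in `b_A` and `b_B` hosts and jointly in
`b_AB`, the co-occurrence score is the Sorensen-Dice form

$$S = \frac{2\,b_{AB}}{b_A + b_B},$$

which is 1 iff the two strains occupy exactly the same non-empty host set
and 0 iff they never co-occur. The same form applied to hosts' strain
sets gives the bee-bee similarity heatmap (`bee_similarity_matrix()`);
the published description of the host heatmap pins down only the
endpoints (1 = identical strain sets), which Dice satisfies, so Dice was
chosen to mirror the strain score.

`mcl_cluster()` is a from-scratch Markov clustering implementation:
self-loops (weight 1) are added, columns normalized, then expansion
(matrix power 2) alternates with inflation (entrywise power, default
`I = 2`, then column renormalization) and pruning of entries below
`1e-5`, until the maximum entry change drops below `1e-8` or 200
iterations pass. Clusters are the supports of attractor rows of the limit
matrix; a node claimed by several supports goes to the largest cluster,
ties broken by the lexicographically smallest member id. These numerical
constants are not prescribed by the source method; they are standard MCL
practice, exposed as arguments, and the test suite verifies partition
agreement with an independent Python/numpy reference implementation
across the inflation sweep 1.2/2/4/6. Inflation 2.0 is the analysis
default; `mcl_sweep()` runs the canonical sweep.

A cluster counts as present in a host iff at least one member strain is
present — the natural reading for "clusters per bee" distributions. The
within- versus between-cluster SNP contrast uses a two-sided Wilcoxon
rank-sum test computed in-package (normal approximation with tie
correction, no continuity correction), cross-checked in the tests against
`stats::wilcox.test()`.

## Permutation machinery

All three association tests share one design: a discrepancy statistic is
the chi-square distance between observed category counts and their mean
under randomization, and the p-value is the upper tail of the *observed
statistic within the randomization distribution of the same statistic*
(add-one estimator, `(1 + #\{null \ge obs\}) / (n_{reps} + 1)`). The
chi-square reference distribution is not used for the p-value: expected
counts estimated from permutations do not follow the textbook chi-square
null, whereas the permutation p-value is valid by construction. The
nominal degrees of freedom are still reported for orientation.

* **Geography** (`location_shuffle_test()`): observed distinct-strain
  counts per location versus random reallocation of hosts to locations
  with location sizes preserved. Bonferroni factor = number of markers
  tested in the run.
* **Reassortment** (`reassortment_null()`): the distribution of pairwise
  co-occurrence counts versus a null that redraws each host's strain set,
  preserving the host's richness and weighting draws by overall strain
  prevalence (without replacement within a host). Histogram categories
  are merged until every expected count is at least 5.
* **Interspecies** (`interspecies_association_test()`): cross-marker pair
  co-occurrence counts over the shared hosts. The null here permutes the
  *host alignment* between the two markers' compositions rather than
  reassorting strains within markers: strains travel in tight clusters
  within a marker, and a per-strain reassortment null destroys that
  structure, making the test reject even when the two markers are
  assembled independently. Permuting which host's composition of marker Y
  accompanies which host's composition of marker X preserves each
  marker's internal structure exactly and randomizes only the
  cross-marker pairing, so independence is the actual null hypothesis
  being tested.

The number of randomizations is not stated by the source method; the
default is 1,000 and every test is reproducible bit for bit given its
seed.

**Saturation curves** (`saturation_curve()`) use the accumulation-curve
scheme: each of `n_combinations` (default 100) replicates draws a random
permutation of the hosts, and the size-*k* value is the number of
distinct strains among the first *k* hosts of that permutation. Every
prefix is a uniformly random nonredundant *k*-subset, each realized curve
is monotone non-decreasing, and the full-size value equals the total
strain count exactly. (Independent subsets per *k* would estimate the
same means but can produce non-monotone realizations.)

## Sequence-evolution simulations

Two in-silico experiments probe whether identical haplotypes in different
hosts could arise without transmission. `simulate_strain_set()` generates,
for each of `n_bees` hosts, `strains_per_bee` sequences from the marker
reference; each sequence receives `k ~ Poisson(mean_snps)` substitutions
at distinct positions (no back-mutation within a sequence), with the
substituted base uniform over the three alternatives (the substitution
matrix is otherwise unspecified by the source method). Positions are
drawn either uniformly (PCR-artifact mode) or by first sampling a codon
position class from `codon_weights` and then a uniform site within the
class (purifying-selection mode). `estimate_codon_weights()` recovers
such weights empirically from a strain registry as the fraction of
distinct observed SNPs at each codon position; sites before the
reading-frame offset belong to no codon class and are excluded, while
incomplete terminal codons keep their true positions.

`count_convergence()` counts distinct *non-reference* sequences generated
independently in two or more hosts. Sequences identical to the reference
are excluded (a zero-SNP draw is not evidence of convergent evolution),
and within-host duplicates are reported separately. At the full study
scale — 144 hosts; 6 strains per host for three markers and 16 for the
fourth; Poisson means of about 8 (three markers) and about 20 (the
fourth) on ~450 bp references — the expected number of cross-host
collisions per run is of order 0.02, dominated by single-SNP sequences
(per sequence, `P(k=1) = λe^{-λ}` lands in one of `3L` equiprobable
single-SNP variants). Absence of convergence is therefore the
overwhelmingly likely outcome of any one run, which is the argument the
simulation is designed to make.

The exact per-marker Poisson means are not printed as numerals in the
source; the values 8/8/8/20 used as defaults here are the described
approximate means, fixed once.

## The synthetic-data generator

`make_truth()` plants the structure the analysis assumes: per marker,
`n_clusters` clusters built from founder sequences `between_cluster_snps`
(default 8) substitutions from the reference, each cluster holding
`strains_per_cluster` members within `within_cluster_snps` (default 1)
substitutions of the founder, so members differ pairwise by 1–2 SNPs.
Each cluster carries one relative-abundance profile shared by every host
carrying it (a floored Dirichlet-type draw, so every member sits
comfortably above the calling threshold). Hosts carry one cluster by
default, with a configurable fraction (default 0.1) carrying a second at
30% weight; with no location bias, assignment is a shuffled round-robin,
which guarantees every cluster is carried when hosts outnumber clusters.
`location_bias = 1` makes clusters exclusive to a home location so the
geography test has a planted positive control.

`simulate_reads()` draws per-(host, marker) coverage from a negative
binomial (mean `coverage_mean`, size `coverage_dispersion`, default 10 —
the emulated study reports a ~46,000-read mean and visible variability
but no distribution), allocates reads multinomially by the host's
profile, and applies independent per-base substitution errors (default
0.001, a typical post-merge Illumina rate). Erroneous bases get
`phred_low` qualities and correct bases `phred_high`, so the quality
filter can be exercised deliberately. Output is standard Phred+33 FASTQ,
deterministic byte for byte given the seed.

What the generator does **not** emulate: chimeras and PCR jackpot
amplification, indel errors (the pipeline discards length-changed reads
anyway), paired-end merge artifacts, quality-value correlation along
reads, and contamination. Recovery results on synthetic data therefore
show the pipeline's correctness under its own model assumptions, not
robustness to every real-world artifact.

## Problem sizes, numerics and edge cases

The packaged tests run at desk scale by choice: recovery fixtures use 12
hosts at 2,000x coverage with 5 planted clusters of 4 strains;
calibration studies use 200 null replicates at 199 randomizations each;
evolution simulations run at the full 144-host scale (a few seconds per
run). Scaling coverage down leaves every frequency-threshold relationship
intact because thresholds are proportions.

Degenerate inputs are handled explicitly: empty read sets produce an
empty table with a warning; markers with fewer than two observed strains
yield an empty co-occurrence graph; a single cluster makes the
within/between contrast inapplicable (flagged, not an error); a
single-strain table makes the reassortment null inapplicable; hosts with
no called strains appear as missing rows in the similarity matrix; and a
cluster of size one simply contributes no within-cluster pairs.

Known limitations: the exact-length alignment proxy assumes merged,
full-length amplicons (it is not suitable for partial or soft-clipped
reads); the permutation chi-square tests are conditional on the observed
table and can be conservative when the count statistic has very few
attainable values (e.g., all clusters exactly the same size); and MCL on
overlapping attractor systems resolves ties by a deterministic rule that
is one of several defensible conventions.
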