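---
title: "Detecting kataegis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting kataegis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kataegisr)
```

## The phenomenon and the statistic

Kataegis is localized hypermutation: showers of substitutions at C:G pairs,
concentrated over kilobase-scale stretches, strand coordinated (almost all
at C, or almost all at G, on the reference strand), and strongly enriched
for a cytidine-deaminase sequence context. It arises when an AID/APOBEC
enzyme deaminates cytosines processively along a stretch of transiently
single-stranded DNA — for example the resected flank of a double-strand
break — so the mutations it leaves behind are much more closely spaced than
a random scatter of the same number of mutations over the genome.

The detection statistic is the intermutational distance (IMD): for each
mutation, the distance in bp to the next downstream mutation on the same
chromosome within the same genome (clone). The most downstream mutation of
each chromosome, and mutations alone on their chromosome, have no IMD.
In a mutagenized genome the IMD distribution is bimodal on a log scale:
a *distal* mode whose spacing matches uniform random placement, and a
*proximal* mode of closely spaced cluster members.

## The detection model

`kataegis()` fits the chain:

1. **`compute_imds()`** — IMDs per clone and chromosome.
2. **`partition_imds()`** — one-dimensional 2-means on `log10(IMD)`. The
   group with the smaller median is *proximal*, the other *distal*.
3. **`derive_threshold()`** — the calling threshold is the empirical
   `1 - exclusion` quantile of the distal IMDs (linear interpolation
   between order statistics). With the default `exclusion = 0.99`, 99% of
   distal (randomly spaced) IMDs exceed the threshold, so the threshold
   marks spacing that random scatter rarely produces.
4. **`call_clusters()`** — a cluster is a maximal run of at least
   `min_mutations` (default 5) consecutive mutations whose internal gaps
   are all strictly below the threshold.

The threshold is always estimated from the pooled IMDs of a whole catalog
(all clones of a genotype), not per clone: per-clone IMD sets are small and
a clone's own clusters would otherwise distort its threshold.

### Numerical choices

* **Scale and initialization of the 2-means step.** The split runs on
  `log10(IMD)` because the bimodality is multiplicative: proximal spacings
  live around 10^2–10^3 bp, distal around 10^4–10^6 bp. Lloyd iteration is
  started deterministically at the 10th and 90th percentiles of the log
  distances, so the fit has no seed sensitivity; on well-separated bimodal
  data this converges to the optimal 1-D two-group split (the test suite
  verifies agreement with an exhaustive split search). A set of identical
  IMDs is a degenerate input and is rejected with an error.
* **Strictness and ties.** "Below the threshold" is strict: a gap exactly
  equal to the threshold breaks a run. A run of five mutations has four
  internal gaps; requiring five gaps would imply six mutations, which
  contradicts clusters of exactly five members, so the four-gap reading is
  used.
* **Cluster length** is `end - start` in bp (not `+ 1`); spans are
  reported on the kb scale where the one-base difference is immaterial,
  but the convention is fixed so tests are unambiguous.
* **Quantile rule.** The threshold quantile interpolates linearly between
  order statistics at rank `(n - 1) * (1 - exclusion)` (the default rule of
  `stats::quantile`); a constant distal sample collapses to that constant.
* Clusters are never merged across chromosomes or clones, and duplicate
  (clone, chromosome, position) records are rejected outright because they
  would produce an IMD of zero.

## The Monte Carlo null

`estimate_cluster_probability()` scatters `n` distinct positions uniformly
over the concatenated genome (chromosome chosen in proportion to its
length), runs the *same* `call_clusters()` code path as the real analysis,
and reports the fraction of simulated clones with at least one call, with
an exact binomial 95% CI. Simulated clones are batched into shared catalogs
under distinct clone ids purely for speed; calling is per clone, so
batching cannot change a call (asserted by a test). At the study scale —
25 mutations on a ~12.1-Mb, 16-chromosome genome, 8.5-kb threshold,
minimum 5 — the estimated probability is on the order of 10^-5, far below
the 10^-3 design bound for the 5-mutation minimum.

Two closed forms anchor the simulation: the mean internal spacing of `n`
uniform points on a chromosome of length `L` is `L / (n + 1)`, and in the
sparse limit the spacing distribution approaches an exponential with rate
`n / L`. The suite checks both (the Kolmogorov–Smirnov distance to the
exponential stays below 0.02 at `n = 100`, `L = 10` Mb).

Null comparison replicates the *observed per-clone mutation counts*
(`simulate()` on a fit) rather than a pooled mean, because mutation loads
vary widely between clones and the IMD distribution is clone-conditional.

## Spectra, polarity and context signatures

All C:G-pair mutations are represented as changes at C (pyrimidine
orientation): a G>A record is a C>T on the minus strand, and its flanking
context is read as the reverse complement. C>T is the transition
(replication across uracil); C>G and C>A are transversions (replication
across the abasic site left by uracil excision, with REV1 inserting C
opposite the lesion — hence the C>G bias). A:T-pair mutations are counted
in totals but never enter C-context or spectrum-at-C statistics.

A cluster's *polarity* is the fraction of members presenting the majority
reference base (C or G); the aggregate strand coordination reported by
`summary()` weights per-cluster polarities by member count, i.e. it is the
fraction of all clustered mutations lying on their cluster's majority
strand. (An unweighted average of per-cluster polarities is a defensible
alternative reading; the weighted form is used because it is the fraction
of *mutations* that are strand coordinated.)

Context preference is summarized as a position frequency matrix over the
-2/-1 flanks of the mutated C. The genomic background
(`genomic_background()`) counts every occurrence of the motif on both
strands — for the TC motif, plus-strand `TC` and plus-strand `GA` (the
minus-strand TC) — so that background normalization reflects the actual
supply of target sites. Normalization divides each observed frequency by
its background frequency and renormalizes the column; an observed column
equal to the background becomes uniform.

PFMs are compared with the Sandelin–Wasserman column score
`sum_col (2 - sum_b (p1 - p2)^2)`: 2 per column for identical columns, 0
for disjoint point masses. The permutation p-value draws null motifs whose
columns are Dirichlet perturbations of a background composition
(concentration `20 * background`, so null columns scatter around the
background with realistic spread) and reports
`(1 + #{null >= observed}) / (n_perm + 1)`. A published motif-comparison
tool computes its p-values against a database-dependent null that cannot
be reconstructed from a fixed configuration; the Dirichlet scheme is this
package's own fully specified, seedable null, not a claim of equivalence
to any external tool's values.

## What the synthetic generator emulates

`generate_catalog()` reproduces the statistical structure of
deaminase-mutagenized yeast genomes:

* **Genome**: 16 chromosomes with the sacCer3 nuclear lengths
  (~12.07 Mb total), i.i.d. sequence at GC 0.38. Defaults are
  configurable; tests use smaller genomes where full scale adds nothing.
* **Singlets**: per-clone count Poisson with mean 25 (the observed median
  load of the hyperactive-AID clones), placed uniformly over C/G sites;
  a fraction 14/1078 of singlets sit at A:T pairs.
* **Clusters**: per-clone count Poisson with mean 0.65 (26 clusters per
  40 clones). Member count is drawn from 5–26 with geometric decay 0.8.
  Intra-cluster gaps are log-normal with median 727 bp; the log-sd is
  `sqrt(2 * ln(1220/727))` ≈ 1.02 so that the mean/median ratio matches
  the observed 1220/727 (the family itself is a modelling choice: the
  observed spacings are positive and heavy-tailed, and only the median and
  mean are known). A draw of gaps is accepted when its span falls in
  1.8–30 kb, which concentrates typical spans at 6–15 kb.
* **Strand coordination**: each cluster has a planted strand; each member
  follows it with probability 0.88.
* **Context**: each member's -2/-1 context is first *sampled from the
  preset PFM*, then the nearest site carrying that context within the
  span is used (nearest C/G site of the right strand as a fallback).
  Sampling the context first, rather than weighting eligible sites by the
  PFM, makes the realized context frequencies match the planted PFM
  instead of the PFM tilted by genomic context availability — which is
  what lets signature recovery be tested against the preset exactly.
* **Spectra**: alternate alleles follow the genotype preset mixes
  (kataegic 46:47:7 and unclustered 87:11:2 for the wild-type AID preset;
  99.3:0.2:0.5 for the UNG-deficient preset, with fourfold load and
  strongly reduced cluster rate; pure C>T for the REV1-deficient preset).
  Cluster span, member count and gap draws are independent; their joint
  distribution in real data is unknown and is not modelled.

What the generator does **not** emulate: real yeast sequence composition
(repeats, GC heterogeneity, nucleosome structure), replication-timing or
transcription-coupled mutation-rate variation, selection (the real clones
were selected for a resistance phenotype, which enriches mutations near
the selected locus), and any mechanistic coupling between break repair and
cluster placement. Passing recovery tests therefore shows the *pipeline*
is correct under the stated statistical structure, not that real genomes
satisfy that structure.

## Problem sizes used by the test and acceptance runs

The suite verifies calling against exhaustive enumeration on 1,000 random
catalogs of up to 50 mutations; recovery of planted clusters on 200
simulated clones at the default study conditions (sensitivity ≥ 0.95,
per-call FDR ≤ 0.05); mixture-median recovery on 500 + 500 log-normal
draws across 10 seeds; spectrum and PFM recovery at ≥ 5,000 planted sites
(±2 percentage points); preset matching over 20 generated catalogs of
≥ 1,000 sites each; and the Monte Carlo false-positive probability over
100,000 simulated clones. These sizes give comfortable statistical margins
for every stated tolerance while keeping a full run to minutes on one CPU.

## Known limitations

* The two-group IMD split assumes bimodality. A catalog with no clusters
  still yields a "proximal" group (the lower tail of random spacing);
  downstream calling is then protected by the minimum-run rule, but the
  reported proximal median is not evidence of clustering by itself.
* Threshold derivation assumes the distal group is dominated by random
  spacing; heavily clustered catalogs (most mutations kataegic) would
  contaminate it.
* The permutation p-value for motif similarity is calibrated against its
  own Dirichlet null only.
* VCF import handles single-allelic substitution records with per-sample
  genotypes; structural and multi-allelic records are rejected, not
  decomposed.
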