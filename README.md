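# kataegisr

Detection and characterization of **kataegis** — localized, strand-coordinated
hypermutation at C:G pairs — in per-clone somatic substitution catalogs, for
researchers analysing AID/APOBEC mutagenesis experiments (e.g. deaminase-
expressing yeast clones) or other small-genome mutation catalogs.

## The statistic at the core

For each mutation, the **intermutational distance** (IMD) is the distance in
bp to the next downstream mutation on the same chromosome within the same
clone. Detection proceeds in four steps:

1. **IMDs** per clone and chromosome.
2. **Two-group split**: 1-D k-means on log10(IMD) divides distances into a
   *proximal* and a *distal* group (the distal group matches random
   scatter).
3. **Threshold**: the empirical (1 − 0.99) quantile of the distal group —
   an IMD that excludes 99% of distal distances.
4. **Cluster call**: a maximal run of ≥ 5 consecutive mutations whose every
   internal gap is strictly below the threshold.

Each call carries its span, strand polarity (fraction of members at the
majority reference base, C or G), and pyrimidine-oriented substitution
spectrum (C→T transitions vs C→G / C→A transversions). A Monte Carlo null
(uniform scatter through the same calling code) bounds the false-positive
probability; −2/−1 flanking-context preferences are summarized as position
frequency matrices and compared with the Sandelin–Wasserman similarity
`Σ_col [2 − Σ_b (p₁(b) − p₂(b))²]` plus a permutation p-value. A synthetic
generator produces yeast-like catalogs with planted clusters and full
ground truth.

## Worked example

```r
library(kataegisr)

params <- kataegis_preset("AID_star", n_clones = 40, seed = 1)
genome <- generate_genome(params)
sim    <- generate_catalog(genome, params)

fit <- kataegis(sim$catalog, genome = genome)
fit
#> kataegis fit
#>   1376 mutations in 40 clone(s); 893 IMD(s)
#>   proximal/distal medians: 830.5 / 177,051 bp
#>   calling threshold: 15,986.5 bp (min 5 mutations)
#>   43 cluster(s) covering 355 mutation(s) in 27 clone(s)

spectrum(as.data.frame(sim$catalog)[unlist(fit$clusters$members), ],
         "kataegic")
#> substitution spectrum [kataegic]: n = 355 (1 at A:T pairs)
#>   C>T 46.0%  C>G 45.5%  C>A 8.5%  (Tv 54.0%)
```

Reading the output: the 40 simulated clones carry 1,376 substitutions whose
IMDs split into a proximal mode (median ~0.8 kb — kataegic spacing) and a
distal mode (median ~177 kb — random scatter on a 12-Mb genome). The
derived threshold calls 43 clusters covering 355 mutations; the clustered
stratum is transversion-rich (54%), the hallmark of abasic-site bypass
within kataegic stretches. `summary(fit)` adds per-clone burdens and the
aggregate strand coordination (0.89 here); `plot(fit)` draws the rainfall
plot; `simulate(fit)` produces count-matched null catalogs;
`predict(fit, newdata)` applies the fitted threshold to a new catalog.

Real data enter through `read_mutation_table()` (TSV with columns
`clone chrom pos ref alt`, or VCF) and `read_genome()` (FASTA or a
`name<TAB>length` table). `run_simulate()` / `run_detect()` / `run_null()` /
`run_signature()` write the corresponding artifact files, and
`inst/scripts/kataegisr-cli.R` exposes them as shell subcommands.

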