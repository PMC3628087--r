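#' Pipeline orchestration
#'
#' Each stage of the analysis is exposed as a `run_*` function that reads
#' standard input files, executes the corresponding module, and writes its
#' artifacts (tables, reports, PFMs) into an output directory together with
#' a JSON echo of the configuration, so a run is fully reproducible from the
#' config and seed. A thin command-line wrapper over these functions ships
#' in `inst/scripts/kataegisr-cli.R`.
#'
#' @name pipeline
NULL

write_config <- function(outdir, stage, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(outdir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the detection stage
#'
#' compute_imds -> partition_imds -> derive_threshold -> call_clusters ->
#' cluster_burden; writes the rainfall table, cluster BED, partition report
#' and burden report.
#'
#' @param catalog_path mutation TSV.
#' @param outdir output directory.
#' @param genome_path optional FASTA or length table.
#' @param exclusion distal exclusion fraction (default 0.99).
#' @param min_mutations minimum cluster size (default 5).
#' @param threshold optional fixed threshold in bp.
#' @return the [kataegis()] fit, invisibly.
#' @export
run_detect <- function(catalog_path, outdir, genome_path = NULL,
                       exclusion = 0.99, min_mutations = 5L,
                       threshold = NULL) {
  genome <- if (!is.null(genome_path)) read_genome(genome_path) else NULL
  catalog <- read_mutation_table(catalog_path, genome = genome)
  fit <- kataegis(catalog, genome = genome, exclusion = exclusion,
                  min_mutations = min_mutations, threshold = threshold)
  write_config(outdir, "detect",
               list(catalog = catalog_path, genome = genome_path,
                    exclusion = exclusion, min_mutations = min_mutations,
                    threshold = threshold))
  write_rainfall_table(fit$catalog, fit$imd,
                       file.path(outdir, "rainfall.tsv"),
                       clusters = fit$clusters)
  write_cluster_bed(fit$clusters, file.path(outdir, "clusters.bed"))
  rep <- c(list(threshold = fit$threshold,
                n_mutations = fit$burden$n_mutations,
                n_imds = nrow(fit$imd$entries)),
           if (!is.null(fit$partition)) list(
             median_proximal = fit$partition$median_proximal,
             median_distal = fit$partition$median_distal,
             n_proximal = fit$partition$n_proximal,
             n_distal = fit$partition$n_distal,
             exclusion = exclusion),
           fit$burden)
  jsonlite::write_json(rep, file.path(outdir, "detect_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Run the Monte Carlo null stage
#'
#' @param genome_path FASTA or length table.
#' @param outdir output directory.
#' @param n_mutations mutations per simulated clone.
#' @param threshold calling threshold in bp.
#' @param min_mutations minimum cluster size.
#' @param n_reps simulated clones.
#' @param seed integer seed.
#' @return the [estimate_cluster_probability()] result, invisibly.
#' @export
run_null <- function(genome_path, outdir, n_mutations = 25L,
                     threshold = 8500, min_mutations = 5L,
                     n_reps = 10000L, seed = 1L) {
  genome <- read_genome(genome_path)
  est <- estimate_cluster_probability(genome, n_mutations, threshold,
                                      min_mutations, n_reps, seed = seed)
  write_config(outdir, "null",
               list(genome = genome_path, n_mutations = n_mutations,
                    threshold = threshold, min_mutations = min_mutations,
                    n_reps = n_reps, seed = seed))
  jsonlite::write_json(
    list(probability = est$probability, ci95 = est$ci95,
         n_hits = est$n_hits, n_reps = est$n_reps, params = est$params),
    file.path(outdir, "null_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(est)
}

#' Run the signature stage
#'
#' Splits the catalog into kataegic and unclustered strata at the supplied
#' (or fitted) threshold, writes per-stratum spectra, the -2/-1 context PFMs
#' (raw and background-normalized), and the Sandelin-Wasserman similarity
#' and permutation p-value of the kataegic PFM against the preset deaminase
#' PFM library.
#'
#' @param catalog_path mutation TSV.
#' @param genome_path FASTA (sequence is required for contexts).
#' @param outdir output directory.
#' @param threshold optional fixed threshold; fitted when NULL.
#' @param min_mutations minimum cluster size.
#' @param n_perm permutations for the similarity p-values.
#' @param seed integer seed.
#' @return a list of stage results, invisibly.
#' @export
run_signature <- function(catalog_path, genome_path, outdir,
                          threshold = NULL, min_mutations = 5L,
                          n_perm = 1000L, seed = 1L) {
  genome <- read_genome(genome_path)
  if (is.null(genome$sequence)) {
    stop("signature stage needs genome sequence (FASTA)")
  }
  catalog <- read_mutation_table(catalog_path, genome = genome)
  fit <- kataegis(catalog, genome = genome, min_mutations = min_mutations,
                  threshold = threshold)
  clustered_idx <- if (nrow(fit$clusters)) unlist(fit$clusters$members)
                   else integer(0)
  strata <- list(
    kataegic = as.data.frame(catalog)[clustered_idx, , drop = FALSE],
    unclustered = as.data.frame(catalog)[setdiff(seq_len(nrow(catalog)),
                                                 clustered_idx), ,
                                         drop = FALSE])
  spectra <- lapply(names(strata), function(s) spectrum(strata[[s]], s))
  spec_df <- do.call(rbind, lapply(spectra, function(sp) {
    data.frame(stratum = sp$stratum, n = sp$n_total,
               n_at_pairs = sp$n_at_pairs,
               CtoT_pct = unname(sp$percent[1]),
               CtoG_pct = unname(sp$percent[2]),
               CtoA_pct = unname(sp$percent[3]))
  }))
  write_config(outdir, "signature",
               list(catalog = catalog_path, genome = genome_path,
                    threshold = threshold, min_mutations = min_mutations,
                    n_perm = n_perm, seed = seed))
  utils::write.table(spec_df, file.path(outdir, "spectra.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  presets <- c("AID_star", "A3A", "A3B", "A3G_star")
  lib <- lapply(presets, function(p) kataegis_preset(p)$context_pfm)
  names(lib) <- presets
  sims <- NULL
  pfms <- list()
  for (s in names(strata)) {
    if (!nrow(strata[[s]])) next
    ctx <- extract_contexts(strata[[s]], genome)
    if (!ctx$n_sites) next
    pfm <- build_pfm(ctx)
    pfms[[s]] <- pfm
    write_pfm(pfm, file.path(outdir, paste0("pfm_", s, ".tsv")))
    bg2 <- genomic_background(genome, offset = -2L, motif = "TC")
    write_pfm(build_pfm(ctx, background = cbind(bg2$composition,
                                                rep(0.25, 4))),
              file.path(outdir, paste0("pfm_", s, "_normalized.tsv")))
    row <- do.call(rbind, lapply(presets, function(p) {
      pv <- sw_pvalue(pfm, lib[[p]], n_perm = n_perm, seed = seed)
      data.frame(stratum = s, preset = p, sw_score = pv$score,
                 p_value = pv$p_value)
    }))
    sims <- rbind(sims, row)
  }
  if (!is.null(sims)) {
    utils::write.table(sims, file.path(outdir, "similarity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(fit = fit, spectra = spectra, pfms = pfms,
                 similarity = sims))
}

#' Run the simulation stage
#'
#' Generates a genome and a synthetic catalog under a genotype preset and
#' writes the FASTA, mutation TSV and ground-truth TSV.
#'
#' @param outdir output directory.
#' @param preset preset name (see [kataegis_preset()]).
#' @param n_clones number of clones.
#' @param seed integer seed.
#' @param ... further overrides for [synthetic_params()].
#' @return the [generate_catalog()] result, invisibly.
#' @export
run_simulate <- function(outdir, preset = "AID_star", n_clones = 40L,
                         seed = 1L, ...) {
  params <- kataegis_preset(preset, n_clones = n_clones, seed = seed, ...)
  genome <- generate_genome(params)
  sim <- generate_catalog(genome, params)
  write_config(outdir, "simulate",
               list(preset = preset, n_clones = n_clones, seed = seed))
  write_genome_fasta(genome, file.path(outdir, "genome.fa"))
  write_mutation_table(sim$catalog, file.path(outdir, "mutations.tsv"))
  write_truth_table(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(sim)
}
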