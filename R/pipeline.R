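# Pipeline orchestration: simulate -> ploidy -> stats -> ld -> karyotype ->
# phylo -> enrich, driven by one config (list or YAML file), with all
# randomness derived from a single top-level seed and a machine-readable
# JSON run report.

#' Default pipeline configuration
#'
#' Returns the full default config as a nested list; [runPipeline()] merges
#' a user config (list or YAML path) over these defaults. The simulation
#' block defines the study conditions (12 clonal lineages at 2-4% pairwise
#' divergence, 7 hybridization events with 2-6 diploid descendants each at
#' 0.05% post-hybridization divergence, negative-binomial depth at 100x with
#' dispersion 10); the analysis block carries the window/threshold defaults
#' of the individual modules.
#'
#' @return Nested list of defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_lineages = 12L, genome_length = 150000L, n_contigs = 1L,
      divergence = 0.03, n_events = 7L,
      descendants_per_event = c(2L, 6L), post_divergence = 5e-4,
      founder_divergence = 0, tetraploid = FALSE,
      depth_mean = 100, depth_dispersion = 10, depth_resolution = 100L,
      metadata_bias = 0.8,
      aneuploid_segments = NULL,   # data.frame strain, contig, start, end, copy
      loh_tracts = NULL),          # data.frame strain, contig, start, end, copy_neutral
    analysis = list(
      depth_window = 30000L, loh_window = 25000L, band_tolerance = 0.15,
      min_run = 5L, loh_het_threshold = 0.1,
      ld_max_dist = 10000L, ld_bin = 100L, ld_span = 0.2,
      n_regions = 50L, region_length = 3000L, max_gap_fraction = 0.15,
      pca_components = 2L),
    enrichment = list(fields = c("habitat", "location"), n_sim = 10000L))
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

canonicalJson <- function(x) {
  sortRec <- function(v) {
    if (is.list(v) && !is.null(names(v))) lapply(v[order(names(v))], sortRec)
    else v
  }
  jsonlite::toJSON(sortRec(x), auto_unbox = TRUE, digits = NA, null = "null")
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(canonicalJson(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a simulated population:
#' synthetic data generation, ploidy classification from simulated assembly
#' statistics, SNP summaries/dissimilarity/PCA, LD decay with the half-max
#' readout, depth/heterozygosity karyotyping, region trees with concordance
#' and hybridization-event grouping, and habitat/geography enrichment. Any
#' stage failure aborts with the partial report attached to the error
#' condition. All randomness derives from the single top-level seed.
#'
#' @param config `NULL` (defaults), a nested list, or a path to a YAML file;
#'   merged over [defaultPipelineConfig()].
#' @param outDir Optional directory; when given, simulated artifacts (VCF,
#'   region FASTAs, depth TSVs, assembly/metadata TSVs, truth JSON) and the
#'   run report are written there.
#' @return list of class `RunReport` (per-stage status, ploidy calls, LD
#'   summary, segment counts, event count, enrichment p-values, config hash,
#'   seed).
#' @export
runPipeline <- function(config = NULL, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config %||% list())
  seed <- as.integer(cfg$seed)
  report <- list(seed = seed, config_hash = configHash(cfg),
                 stages = list())
  sim <- cfg$simulate
  ana <- cfg$analysis

  # --- simulate ---------------------------------------------------------
  hap <- simulateClonalHaploids(sim$n_lineages, sim$genome_length,
                                divergence = sim$divergence,
                                nContigs = sim$n_contigs,
                                seed = childSeed(seed, "haploids"))
  pop <- plantHybridizations(hap, sim$n_events,
                             descendantsPerEvent = sim$descendants_per_event,
                             postDivergence = sim$post_divergence,
                             founderDivergence = sim$founder_divergence,
                             tetraploid = sim$tetraploid,
                             seed = childSeed(seed, "hybrids"))
  gm <- genotypeMatrix(pop)
  lohOut <- plantLOH(gm, sim$loh_tracts, seed = childSeed(seed, "loh"))
  gm <- lohOut$genotypes
  meta <- simulateMetadata(pop, bias = sim$metadata_bias,
                           seed = childSeed(seed, "meta"))
  truePloidy <- setNames(pop$truth$strains$ploidy, pop$truth$strains$strain_id)
  stats <- simulateAssemblyStats(unname(truePloidy),
                                 seed = childSeed(seed, "assembly"))
  stats$strain_id <- names(truePloidy)
  cm <- contigMap(pop$genomeLength, pop$nContigs)
  contigLengths <- setNames(cm$end - cm$start, cm$contig)
  segs <- sim$aneuploid_segments
  depthTracks <- lapply(names(truePloidy), function(s) {
    ds <- NULL
    if (!is.null(segs) && nrow(segs))
      ds <- segs[segs$strain == s, c("contig", "start", "end", "copy")]
    if (nrow(lohOut$depthSegments))
      ds <- rbind(ds, lohOut$depthSegments[
        lohOut$depthSegments$strain == s,
        c("contig", "start", "end", "copy")])
    simulateDepth(truePloidy[[s]], contigLengths, segments = ds,
                  depthMean = sim$depth_mean,
                  dispersion = sim$depth_dispersion,
                  resolution = sim$depth_resolution,
                  seed = childSeed(seed, paste0("depth:", s)))
  })
  names(depthTracks) <- names(truePloidy)
  alns <- regionAlignments(pop, nRegions = ana$n_regions,
                           regionLength = ana$region_length)
  report$stages$simulate <- "ok"

  # --- ploidy -----------------------------------------------------------
  calls <- classifyPloidy(stats)
  report$ploidy_calls <- setNames(calls$call, calls$strain_id)
  report$stages$ploidy <- "ok"

  # --- stats ------------------------------------------------------------
  summaries <- snpSummaries(gm, pop$genomeLength)
  pca <- genotypePca(gm, nComponents = ana$pca_components)
  report$snp_summary <- list(
    mean_haploid_total_density = mean(
      summaries$total_snp_density[truePloidy[summaries$strain_id] == 1]),
    mean_diploid_het_density = mean(
      summaries$het_snp_density[truePloidy[summaries$strain_id] == 2]),
    pca_variance_pc1_pc2 = sum(pca$varianceExplained[1:2]))
  report$stages$stats <- "ok"

  # --- ld ---------------------------------------------------------------
  ld <- ldDecay(gm, maxDist = ana$ld_max_dist, binWidth = ana$ld_bin,
                smootherSpan = ana$ld_span)
  report$ld <- list(max_observed = ld$maxObserved, half_max = ld$halfMax,
                    half_decay_distance =
                      if (is.na(ld$halfDecayDistance)) "not reached"
                      else ld$halfDecayDistance)
  report$stages$ld <- "ok"

  # --- karyotype --------------------------------------------------------
  nAneu <- 0L; nLoh <- 0L
  for (s in names(truePloidy)) {
    track <- windowDepth(depthTracks[[s]], windowSize = ana$depth_window)
    aneu <- callAneuploidSegments(track, truePloidy[[s]],
                                  bandTolerance = ana$band_tolerance,
                                  minRun = ana$min_run)
    nAneu <- nAneu + length(aneu)
    if (truePloidy[[s]] >= 2) {
      het <- try(windowHeterozygosity(gm, s, contigLengths = contigLengths,
                                      windowSize = ana$loh_window),
                 silent = TRUE)
      if (!inherits(het, "try-error")) {
        loh <- callLohSegments(het, track,
                               hetThreshold = ana$loh_het_threshold,
                               bandTolerance = ana$band_tolerance,
                               minRun = ana$min_run)
        nLoh <- nLoh + length(loh)
      }
    }
  }
  report$karyotype <- list(n_aneuploid_segments = nAneu,
                           n_loh_segments = nLoh)
  report$stages$karyotype <- "ok"

  # --- phylo ------------------------------------------------------------
  ploidyVec <- truePloidy
  regs <- selectRegions(alns, ploidyVec, n = ana$n_regions,
                        maxGapFraction = ana$max_gap_fraction)
  trees <- lapply(regs, regionTree)
  conc <- concordanceScore(trees)
  D <- averageSubgenomeDistance(regs)
  asg <- assignSubgenomes(D)
  events <- inferHybridEvents(asg, D)
  report$phylo <- list(n_region_trees = length(trees),
                       concordance = conc,
                       n_event_groups = nrow(events$groups),
                       n_unplaced = length(events$unplaced))
  report$stages$phylo <- "ok"

  # --- enrich -----------------------------------------------------------
  groupOf <- setNames(rep(NA_character_, length(truePloidy)),
                      names(truePloidy))
  for (k in seq_len(nrow(events$groups))) {
    for (m in strsplit(events$groups$members[k], ",")[[1]])
      groupOf[[m]] <- events$groups$event_id[k]
  }
  groupOf[names(truePloidy)[truePloidy == 1]] <- "haploid"
  report$enrichment <- lapply(setNames(nm = cfg$enrichment$fields), function(f) {
    res <- testGroupEnrichment(meta, groupOf, field = f,
                               nSim = cfg$enrichment$n_sim,
                               seed = childSeed(seed, paste0("enrich:", f)))
    list(p_value = res$p.value, excluded = res$excluded)
  })
  report$stages$enrich <- "ok"

  # --- artifacts --------------------------------------------------------
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGenotypeVcf(gm, file.path(outDir, "genotypes.vcf"))
    writeRegionAlignments(alns, file.path(outDir, "regions"))
    dir.create(file.path(outDir, "depth"), showWarnings = FALSE)
    for (s in names(depthTracks))
      writeDepthTsv(depthTracks[[s]],
                    file.path(outDir, "depth", paste0(s, ".tsv")))
    write.table(stats, file.path(outDir, "assembly_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(meta, file.path(outDir, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(events = pop$truth$events,
                              strains = pop$truth$strains),
                         file.path(outDir, "truth.json"), dataframe = "rows")
    writeRunReport(structure(report, class = "RunReport"),
                   file.path(outDir, "report.json"))
  }
  structure(report, class = "RunReport")
}

#' Write a run report as JSON
#'
#' @param report A `RunReport` from [runPipeline()].
#' @param path Output path.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed", x$seed, ", config", substr(x$config_hash, 1, 8), ")\n")
  cat("  stages:", paste(names(x$stages), unlist(x$stages), sep = "=",
                         collapse = ", "), "\n")
  cat("  event groups:", x$phylo$n_event_groups,
      "| concordance:", round(x$phylo$concordance, 3), "\n")
  cat("  LD half-decay:", as.character(x$ld$half_decay_distance), "\n")
  invisible(x)
}
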