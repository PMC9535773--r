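# Synthetic clonal populations with planted hybridization events, aneuploidy,
# LOH tracts, depth profiles and assembly statistics — with full ground truth,
# so every downstream stage of the pipeline is testable without sequencing
# data. Mutation model is infinite-sites: every site mutates at most once in
# the whole simulated history (a global used-site pool is threaded through).

DNA_BASES <- c("A", "C", "G", "T")

sampleFreeSites <- function(n, genomeLength, used) {
  if (n == 0) return(integer(0))
  free <- setdiff(seq_len(genomeLength) - 1L, used)
  if (length(free) < n)
    stop("genome too small: requested ", n, " new mutations but only ",
         length(free), " unmutated sites remain (infinite-sites violated)")
  sample(free, n)
}

mutationTable <- function(sites, ancestral) {
  if (!length(sites))
    return(data.frame(site = integer(0), base = character(0)))
  base <- vapply(sites, function(s) {
    sample(setdiff(DNA_BASES, ancestral[s + 1L]), 1L)
  }, character(1))
  data.frame(site = as.integer(sites), base = base, stringsAsFactors = FALSE)
}

# Merge inherited mutations with new ones (new ones are at fresh sites by
# construction, so this is a plain row-bind kept sorted by site).
addMutations <- function(muts, extra) {
  out <- rbind(muts, extra)
  out[order(out$site), , drop = FALSE]
}

#' Simulate a clonal set of haploid lineages
#'
#' Draws a random bifurcating genealogy (pure-birth Yule process) over
#' `nLineages` haploid lineages, rescales it so that the mean pairwise path
#' length equals the target `divergence`, and drops mutations on the branches
#' by a Poisson process over `genomeLength` sites under the infinite-sites
#' model. With no recombination every locus shares this one genealogy — the
#' defining property of a clonal population.
#'
#' @param nLineages Number of haploid lineages (>= 2).
#' @param genomeLength Genome length in bp.
#' @param divergence Expected pairwise difference fraction between two random
#'   lineages (default 0.03, i.e. 3%, matching the 2-4% between-lineage
#'   divergence seen between hybridizing black-yeast genomes).
#' @param nContigs Number of equal-sized contigs the genome is split into.
#' @param seed Integer seed; fixes all randomness.
#' @return An object of class `HaploidPopulation`: list with the lineage
#'   `tree` (tip labels `L01`, `L02`, ...), per-lineage mutation tables
#'   (`haplotypes`), the `ancestral` sequence, `genomeLength`, `nContigs`,
#'   and the global `usedSites` pool.
#' @export
simulateClonalHaploids <- function(nLineages, genomeLength = 150000,
                                   divergence = 0.03, nContigs = 1L,
                                   seed = 1L) {
  if (nLineages < 2) stop("nLineages must be >= 2")
  withSeed(seed, {
    tree <- ape::rphylo(nLineages, birth = 1, death = 0)
    tree$tip.label <- sprintf("L%02d", seq_len(nLineages))
    d <- ape::cophenetic.phylo(tree)
    tree$edge.length <- tree$edge.length * divergence / mean(d[upper.tri(d)])
    expMut <- sum(tree$edge.length) * genomeLength
    if (expMut > genomeLength)
      stop("genome_length too small for requested divergence: expected ",
           round(expMut), " segregating sites exceed ", genomeLength, " sites")
    ancestral <- sample(DNA_BASES, genomeLength, replace = TRUE)
    nTip <- nLineages
    root <- nTip + 1L
    nodeMuts <- vector("list", nTip + tree$Nnode)
    nodeMuts[[root]] <- data.frame(site = integer(0), base = character(0))
    used <- integer(0)
    ord <- reorder(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
      nmut <- rpois(1, ord$edge.length[k] * genomeLength)
      sites <- sampleFreeSites(nmut, genomeLength, used)
      used <- c(used, sites)
      nodeMuts[[child]] <- addMutations(nodeMuts[[par]],
                                        mutationTable(sites, ancestral))
    }
    haplotypes <- nodeMuts[seq_len(nTip)]
    names(haplotypes) <- tree$tip.label
    structure(list(tree = tree, haplotypes = haplotypes, ancestral = ancestral,
                   genomeLength = as.integer(genomeLength),
                   nContigs = as.integer(nContigs), usedSites = used,
                   seed = as.integer(seed)),
              class = "HaploidPopulation")
  })
}

#' @export
print.HaploidPopulation <- function(x, ...) {
  cat("HaploidPopulation:", length(x$haplotypes), "clonal lineages,",
      x$genomeLength, "bp genome,",
      length(x$usedSites), "segregating sites\n")
  invisible(x)
}

#' Plant intraspecific hybridization events
#'
#' Fuses pairs of distinct haploid lineages into stable F1 diploids: each
#' event spawns several diploid descendant strains that independently
#' accumulate post-hybridization mutations on both subgenomes. No meiosis
#' ever occurs — subgenomes never recombine with each other, mirroring
#' hybrids stuck at the F1 stage. Optionally one tetraploid is formed by
#' fusing two diploids from two named events (emulating a diploid x diploid
#' hybridization).
#'
#' @param pop A `HaploidPopulation` from [simulateClonalHaploids()].
#' @param nEvents Number of hybridization events.
#' @param pairs Optional 2 x nEvents matrix of lineage indices; by default
#'   distinct unordered pairs are sampled without replacement.
#' @param descendantsPerEvent Integer range `c(min, max)` of diploid
#'   descendants per event.
#' @param postDivergence Expected pairwise difference fraction between two
#'   descendants of the same event (default 5e-4, i.e. 0.05% — two orders of
#'   magnitude below the between-lineage divergence, so event recovery is
#'   well-posed).
#' @param founderDivergence Expected per-subgenome founder-private difference
#'   fraction (default 0). Gives each event its own private mutations, which
#'   makes two events on the *same* lineage pair distinguishable.
#' @param tetraploid `FALSE`, or a length-2 vector of event indices whose
#'   first descendants are fused into one tetraploid strain.
#' @param seed Integer seed.
#' @return An object of class `HybridPopulation`: haploid strains (one per
#'   lineage, named after it) plus diploid descendants (`D<event>.<k>`) and
#'   optionally the tetraploid `T1`, with a `truth` record of class
#'   `SimulationTruth`.
#' @export
plantHybridizations <- function(pop, nEvents, pairs = NULL,
                                descendantsPerEvent = c(2L, 6L),
                                postDivergence = 5e-4, founderDivergence = 0,
                                tetraploid = FALSE, seed = 1L) {
  stopifnot(inherits(pop, "HaploidPopulation"))
  nL <- length(pop$haplotypes)
  L <- pop$genomeLength
  maxPairs <- choose(nL, 2)
  if (nEvents > maxPairs)
    stop("nEvents exceeds the number of distinct unordered lineage pairs (",
         maxPairs, ")")
  withSeed(seed, {
    if (is.null(pairs)) {
      all <- combn(nL, 2)
      pairs <- all[, sample.int(ncol(all), nEvents), drop = FALSE]
    } else {
      pairs <- as.matrix(pairs)
      if (ncol(pairs) != nEvents) stop("pairs must have one column per event")
    }
    if (any(pairs[1, ] == pairs[2, ]))
      stop("hybridization between identical lineages is excluded ",
           "(intraspecific selfing)")
    used <- pop$usedSites
    lin <- names(pop$haplotypes)
    newMuts <- function(rate) {
      n <- rpois(1, rate * L)
      sites <- sampleFreeSites(n, L, used)
      used <<- c(used, sites)
      mutationTable(sites, pop$ancestral)
    }
    strains <- lapply(lin, function(l) {
      list(id = l, ploidy = 1L, subgenomes = list(a = pop$haplotypes[[l]]),
           parents = l, event = NA_character_)
    })
    names(strains) <- lin
    events <- data.frame(event_id = character(0), parent_a = character(0),
                         parent_b = character(0), n_descendants = integer(0))
    for (e in seq_len(nEvents)) {
      pa <- lin[pairs[1, e]]; pb <- lin[pairs[2, e]]
      eid <- sprintf("E%02d", e)
      fa <- addMutations(pop$haplotypes[[pa]], newMuts(founderDivergence))
      fb <- addMutations(pop$haplotypes[[pb]], newMuts(founderDivergence))
      nDesc <- if (descendantsPerEvent[1] == descendantsPerEvent[2])
        descendantsPerEvent[1]
      else sample(seq(descendantsPerEvent[1], descendantsPerEvent[2]), 1)
      for (k in seq_len(nDesc)) {
        id <- sprintf("D%d.%d", e, k)
        strains[[id]] <- list(
          id = id, ploidy = 2L,
          subgenomes = list(a = addMutations(fa, newMuts(postDivergence / 2)),
                            b = addMutations(fb, newMuts(postDivergence / 2))),
          parents = c(pa, pb), event = eid)
      }
      events <- rbind(events, data.frame(event_id = eid, parent_a = pa,
                                         parent_b = pb,
                                         n_descendants = nDesc))
    }
    if (!isFALSE(tetraploid)) {
      ev <- as.integer(tetraploid)
      if (length(ev) != 2 || any(ev > nEvents))
        stop("tetraploid must name two planted events")
      d1 <- strains[[sprintf("D%d.1", ev[1])]]
      d2 <- strains[[sprintf("D%d.1", ev[2])]]
      sub <- c(d1$subgenomes, d2$subgenomes)
      sub <- lapply(sub, function(s) addMutations(s, newMuts(postDivergence / 2)))
      names(sub) <- letters[1:4]
      strains[["T1"]] <- list(id = "T1", ploidy = 4L, subgenomes = sub,
                              parents = c(d1$parents, d2$parents),
                              event = paste(sprintf("E%02d", ev), collapse = "+"))
    }
    truthStrains <- do.call(rbind, lapply(strains, function(s) {
      data.frame(strain_id = s$id, ploidy = s$ploidy,
                 event_id = if (is.na(s$event)) NA_character_ else s$event,
                 lineages = paste(s$parents, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    rownames(truthStrains) <- NULL
    truth <- structure(list(tree_newick = ape::write.tree(pop$tree),
                            events = events, strains = truthStrains,
                            aneuploid_segments = NULL, loh_tracts = NULL),
                       class = "SimulationTruth")
    structure(list(tree = pop$tree, ancestral = pop$ancestral,
                   genomeLength = L, nContigs = pop$nContigs,
                   strains = strains, truth = truth, usedSites = used,
                   seed = as.integer(seed)),
              class = "HybridPopulation")
  })
}

#' @export
print.HybridPopulation <- function(x, ...) {
  pl <- vapply(x$strains, `[[`, integer(1), "ploidy")
  cat("HybridPopulation:", sum(pl == 1), "haploid,", sum(pl == 2), "diploid,",
      sum(pl == 4), "tetraploid strain(s);",
      nrow(x$truth$events), "planted hybridization event(s)\n")
  invisible(x)
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat("SimulationTruth:", nrow(x$events), "event(s),",
      nrow(x$strains), "strain(s)\n")
  invisible(x)
}

# contig decomposition of the [0, genomeLength) coordinate line
contigMap <- function(genomeLength, nContigs) {
  bounds <- floor(seq(0, genomeLength, length.out = nContigs + 1))
  data.frame(contig = sprintf("ctg%02d", seq_len(nContigs)),
             start = as.integer(bounds[-length(bounds)]),
             end = as.integer(bounds[-1]))
}

#' Extract phased per-region haplotype alignments
#'
#' Cuts `nRegions` non-overlapping windows out of the simulated genome and
#' materializes the aligned subgenome sequences of every strain. Sequence
#' names follow the multilabel convention: plain strain id for haploids,
#' strain id plus subgenome letter (`"D1.2a"`) for ploidy > 1.
#'
#' @param pop A `HybridPopulation` (or `HaploidPopulation`).
#' @param nRegions Number of regions.
#' @param regionLength Region length in bp; `nRegions * regionLength` must
#'   fit in the genome.
#' @return Named list of [Biostrings::DNAStringSet] alignments
#'   (`r01` ... `r<n>`).
#' @export
regionAlignments <- function(pop, nRegions = 50L, regionLength = 3000L) {
  L <- pop$genomeLength
  if (nRegions * regionLength > L)
    stop("nRegions * regionLength exceeds the genome length")
  strains <- if (inherits(pop, "HaploidPopulation")) {
    lapply(names(pop$haplotypes), function(l)
      list(id = l, ploidy = 1L, subgenomes = list(a = pop$haplotypes[[l]])))
  } else pop$strains
  step <- L %/% nRegions
  out <- vector("list", nRegions)
  for (r in seq_len(nRegions)) {
    start <- (r - 1L) * step          # 0-based
    idx <- seq.int(start + 1L, start + regionLength)
    seqs <- character(0)
    for (s in strains) {
      multi <- s$ploidy > 1L
      for (letter in names(s$subgenomes)) {
        mu <- s$subgenomes[[letter]]
        sq <- pop$ancestral[idx]
        hit <- mu$site >= start & mu$site < start + regionLength
        if (any(hit)) sq[mu$site[hit] - start + 1L] <- mu$base[hit]
        seqs[[if (multi) paste0(s$id, letter) else s$id]] <-
          paste(sq, collapse = "")
      }
    }
    out[[r]] <- Biostrings::DNAStringSet(seqs)
  }
  names(out) <- sprintf("r%02d", seq_len(nRegions))
  out
}

#' Derive the genotype matrix of a simulated population
#'
#' Collects every segregating site across all subgenomes and reports, per
#' strain, the number of genome copies carrying the derived (non-ancestral)
#' allele. Under infinite sites every site is biallelic and sites where
#' a diploid's two subgenomes disagree are heterozygous.
#'
#' @param pop A `HybridPopulation` or `HaploidPopulation`.
#' @return A [GenotypeMatrix-class] (contigs per `pop$nContigs`).
#' @export
genotypeMatrix <- function(pop) {
  strains <- if (inherits(pop, "HaploidPopulation")) {
    lapply(names(pop$haplotypes), function(l)
      list(id = l, ploidy = 1L, subgenomes = list(a = pop$haplotypes[[l]])))
  } else pop$strains
  allMut <- do.call(rbind, lapply(strains, function(s)
    do.call(rbind, s$subgenomes)))
  sites <- sort(unique(allMut$site))
  if (!length(sites)) stop("no segregating sites in population")
  altBase <- allMut$base[match(sites, allMut$site)]
  dos <- vapply(strains, function(s) {
    counts <- integer(length(sites))
    for (sub in s$subgenomes) {
      hit <- match(sub$site, sites)
      counts[hit] <- counts[hit] + 1L
    }
    counts
  }, integer(length(sites)))
  ploidy <- setNames(vapply(strains, `[[`, integer(1), "ploidy"),
                     vapply(strains, `[[`, character(1), "id"))
  colnames(dos) <- names(ploidy)
  cm <- contigMap(pop$genomeLength, pop$nContigs)
  ci <- findInterval(sites, cm$start)
  lociDf <- data.frame(contig = cm$contig[ci],
                       pos0 = sites - cm$start[ci],
                       ref = pop$ancestral[sites + 1L],
                       alt = altBase, stringsAsFactors = FALSE)
  ord <- order(lociDf$contig, lociDf$pos0)
  GenotypeMatrix(lociDf[ord, ], dos[ord, , drop = FALSE], ploidy)
}

#' Forward Wright-Fisher simulation of a haploid population
#'
#' Constant-size forward-time haploid Wright-Fisher model under infinite
#' sites. With `recombinationRate = 0` each offspring is a clonal copy of one
#' parent (plus new mutations): every locus shares a single genealogy and
#' linkage disequilibrium does not decay with distance. With
#' `recombinationRate > 0` offspring are crossover mosaics of two parents
#' (crossover count Poisson with mean `recombinationRate * genomeLength`),
#' which breaks linkage at a rate increasing with distance.
#'
#' @param nIndividuals Population size N.
#' @param genomeLength Genome length in bp.
#' @param mutationRate Per-base per-generation mutation rate.
#' @param recombinationRate Per-base per-generation crossover rate (0 for
#'   clonal mode).
#' @param nGenerations Number of generations to evolve (>= 1); around 10 N
#'   approaches mutation-drift equilibrium.
#' @param sampleSize Number of haplotypes sampled at the end
#'   (<= `nIndividuals`).
#' @param seed Integer seed.
#' @return A phased haploid [GenotypeMatrix-class] of the sites segregating
#'   in the sample (single contig `"chr1"`; allele 1 is the derived allele).
#' @export
simulateWrightFisher <- function(nIndividuals, genomeLength, mutationRate,
                                 recombinationRate = 0, nGenerations,
                                 sampleSize, seed = 1L) {
  if (sampleSize > nIndividuals) stop("sampleSize must be <= nIndividuals")
  if (nGenerations < 1) stop("nGenerations must be >= 1")
  N <- as.integer(nIndividuals); L <- genomeLength
  withSeed(seed, {
    pop <- matrix(0L, N, 0)
    pos <- integer(0)
    pruneEvery <- 10L
    for (g in seq_len(nGenerations)) {
      parents <- sample.int(N, N, replace = TRUE)
      newpop <- pop[parents, , drop = FALSE]
      if (recombinationRate > 0 && length(pos)) {
        nCross <- rpois(N, recombinationRate * L)
        for (i in which(nCross > 0)) {
          p2 <- sample.int(N, 1)
          cuts <- sort(runif(nCross[i], 0, L))
          fromP2 <- findInterval(pos, cuts) %% 2 == 1
          newpop[i, fromP2] <- pop[p2, fromP2]
        }
      }
      nMut <- rpois(1, N * mutationRate * L)
      if (nMut > 0) {
        sites <- sample.int(L, min(nMut, L)) - 1L
        sites <- sites[!(sites %in% pos)]      # infinite sites: no recurrence
        if (length(sites)) {
          block <- matrix(0L, N, length(sites))
          block[cbind(sample.int(N, length(sites), replace = TRUE),
                      seq_along(sites))] <- 1L
          newpop <- cbind(newpop, block)
          pos <- c(pos, sites)
        }
      }
      pop <- newpop
      if (g %% pruneEvery == 0 || g == nGenerations) {
        cs <- colSums(pop)
        keep <- cs > 0L & cs < N
        pop <- pop[, keep, drop = FALSE]
        pos <- pos[keep]
      }
    }
    idx <- sample.int(N, sampleSize)
    smp <- pop[idx, , drop = FALSE]
    cs <- colSums(smp)
    keep <- cs > 0L & cs < sampleSize
    smp <- smp[, keep, drop = FALSE]; pos <- pos[keep]
    ord <- order(pos)
    ids <- sprintf("h%03d", seq_len(sampleSize))
    GenotypeMatrix(
      data.frame(contig = "chr1", pos0 = pos[ord], ref = "A", alt = "C",
                 stringsAsFactors = FALSE),
      t(smp)[ord, , drop = FALSE],
      setNames(rep(1L, sampleSize), ids))
  })
}

#' Simulate a sequencing-depth track
#'
#' Draws negative-binomial depth values on a regular grid of small bins
#' (default 100 bp). The expected depth of a bin is
#' `depthMean * copy / ploidy`, where the copy number is the strain's
#' baseline ploidy outside planted segments. Negative-binomial rather than
#' Poisson because real short-read coverage is overdispersed.
#'
#' @param ploidy Baseline ploidy of the strain.
#' @param contigLengths Named integer vector of contig lengths (bp).
#' @param segments Optional data.frame `contig, start, end, copy` of planted
#'   aneuploid (or deletion-LOH) segments, 0-based half-open.
#' @param depthMean Genome-wide mean depth at baseline copy number (> 0).
#' @param dispersion Negative-binomial size parameter (default 10; smaller is
#'   noisier).
#' @param resolution Bin width in bp.
#' @param seed Integer seed.
#' @return data.frame `contig, start, end, depth` (a `DepthRaw` track).
#' @export
simulateDepth <- function(ploidy, contigLengths, segments = NULL,
                          depthMean = 100, dispersion = 10, resolution = 100L,
                          seed = 1L) {
  if (depthMean <= 0) stop("depthMean must be > 0")
  if (is.null(names(contigLengths)))
    names(contigLengths) <- sprintf("ctg%02d", seq_along(contigLengths))
  withSeed(seed, {
    out <- lapply(names(contigLengths), function(ct) {
      len <- contigLengths[[ct]]
      starts <- seq.int(0L, len - 1L, by = resolution)
      ends <- pmin(starts + resolution, len)
      copy <- rep(ploidy, length(starts))
      if (!is.null(segments)) {
        for (k in which(segments$contig == ct)) {
          if (segments$start[k] < 0 || segments$end[k] > len)
            stop("planted segment out of contig bounds on ", ct)
          hit <- starts < segments$end[k] & ends > segments$start[k]
          copy[hit] <- segments$copy[k]
        }
      }
      data.frame(contig = ct, start = starts, end = ends,
                 depth = rnbinom(length(starts), size = dispersion,
                                 mu = depthMean * copy / ploidy))
    })
    do.call(rbind, out)
  })
}

#' Plant loss-of-heterozygosity tracts
#'
#' Within each tract, heterozygous sites of the target diploid strain
#' collapse to one allele (the retained allele is drawn per site, emulating
#' the loss of one subgenome's copy). Copy-neutral tracts leave depth
#' untouched; deletion tracts are reported back as depth segments at half the
#' baseline copy number for [simulateDepth()].
#'
#' @param gm A [GenotypeMatrix-class].
#' @param tracts data.frame `strain, contig, start, end, copy_neutral`
#'   (coordinates 0-based half-open).
#' @param seed Integer seed.
#' @return list with `genotypes` (modified `GenotypeMatrix`) and
#'   `depthSegments` (data.frame `strain, contig, start, end, copy` for the
#'   deletion tracts; empty when all tracts are copy-neutral).
#' @export
plantLOH <- function(gm, tracts, seed = 1L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (is.null(tracts) || nrow(tracts) == 0)
    return(list(genotypes = gm, depthSegments =
                  data.frame(strain = character(0), contig = character(0),
                             start = integer(0), end = integer(0),
                             copy = integer(0))))
  pl <- strainPloidy(gm)
  dos <- dosage(gm)
  lo <- loci(gm)
  depthSegs <- list()
  withSeed(seed, {
    for (k in seq_len(nrow(tracts))) {
      tr <- tracts[k, ]
      if (!tr$strain %in% names(pl)) stop("unknown strain ", tr$strain)
      p <- pl[[tr$strain]]
      if (p < 2) stop("LOH tract planted on haploid strain ", tr$strain)
      rows <- which(lo$contig == tr$contig & lo$pos0 >= tr$start &
                    lo$pos0 < tr$end)
      d <- dos[rows, tr$strain]
      het <- !is.na(d) & d > 0L & d < p
      if (any(het)) {
        keepAlt <- runif(sum(het)) < d[het] / p
        d[het] <- ifelse(keepAlt, p, 0L)
        dos[rows, tr$strain] <- d
      }
      if (!isTRUE(as.logical(tr$copy_neutral)))
        depthSegs[[length(depthSegs) + 1L]] <-
          data.frame(strain = tr$strain, contig = tr$contig,
                     start = tr$start, end = tr$end, copy = p %/% 2L)
    }
    list(genotypes = GenotypeMatrix(lo, dos, pl),
         depthSegments = if (length(depthSegs)) do.call(rbind, depthSegs)
         else data.frame(strain = character(0), contig = character(0),
                         start = integer(0), end = integer(0),
                         copy = integer(0)))
  })
}

# Table-3-style per-ploidy distribution parameters for assembly statistics.
assemblyStatParams <- function() {
  list(`1` = list(size = c(26.52e6, 1.47e6), genes = c(9519, 665),
                  copy = c(1.00, 0.03)),
       `2` = list(size = c(49.30e6, 1.74e6), genes = c(20417, 1709),
                  copy = c(1.70, 0.08)),
       `4` = list(size = c(94.67e6, 3.0e6), genes = c(46596, 2500),
                  copy = c(3.10, 0.20)))
}

#' Simulate assembly statistics for strains of known ploidy
#'
#' Draws genome-assembly size, predicted gene count and mean core-BUSCO copy
#' number from per-ploidy normal distributions whose haploid and diploid
#' means/SDs follow the published black-yeast assembly statistics (haploid
#' 26.52 +/- 1.47 Mbp and 9,519 +/- 665 genes; diploid 49.30 +/- 1.74 Mbp and
#' 20,417 +/- 1,709 genes; tetraploid centred on 94.67 Mbp and 46,596 genes).
#'
#' @param ploidy Integer vector of true ploidies (values in 1, 2, 4).
#' @param seed Integer seed.
#' @param truncSD Optional truncation: redraw values further than `truncSD`
#'   standard deviations from their mean.
#' @return data.frame `strain_id, true_ploidy, assembly_size, n_genes,
#'   busco_core_mean_copy`.
#' @export
simulateAssemblyStats <- function(ploidy, seed = 1L, truncSD = NULL) {
  if (!all(ploidy %in% c(1L, 2L, 4L)))
    stop("unsupported ploidy: ", paste(setdiff(ploidy, c(1, 2, 4)), collapse = ","))
  pars <- assemblyStatParams()
  rtn <- function(n, mu, sd) {
    x <- rnorm(n, mu, sd)
    if (!is.null(truncSD)) {
      bad <- abs(x - mu) > truncSD * sd
      while (any(bad)) {
        x[bad] <- rnorm(sum(bad), mu, sd)
        bad <- abs(x - mu) > truncSD * sd
      }
    }
    x
  }
  withSeed(seed, {
    out <- lapply(seq_along(ploidy), function(i) {
      p <- pars[[as.character(ploidy[i])]]
      data.frame(strain_id = sprintf("sim%04d", i),
                 true_ploidy = ploidy[i],
                 assembly_size = rtn(1, p$size[1], p$size[2]),
                 n_genes = round(rtn(1, p$genes[1], p$genes[2])),
                 busco_core_mean_copy = rtn(1, p$copy[1], p$copy[2]))
    })
    do.call(rbind, out)
  })
}

#' Simulate habitat and geography metadata with group bias
#'
#' Assigns each strain an isolation-habitat category and a continent.
#' Every hybridization-event group (and the pooled haploid set) draws a
#' preferred habitat and continent; each member strain receives the
#' preference with probability `bias` and a uniform draw from the remaining
#' categories otherwise. This emulates the skew of lineage composition in
#' favour of specific localities and habitats that the enrichment module is
#' designed to detect.
#'
#' @param pop A `HybridPopulation`.
#' @param habitats Habitat categories to draw from.
#' @param continents Continent labels to draw from.
#' @param bias Probability of receiving the group's preferred category
#'   (default 0.8; 1/k recovers the unbiased null).
#' @param seed Integer seed.
#' @return data.frame `strain_id, habitat, location, ploidy` suitable for
#'   [readStrainTable()]-style consumers (a strain metadata table).
#' @export
simulateMetadata <- function(pop,
                             habitats = c("brine", "bittern", "seawater",
                                          "tap water", "surface"),
                             continents = c("Europe", "Asia", "South America",
                                            "Africa"),
                             bias = 0.8, seed = 1L) {
  stopifnot(inherits(pop, "HybridPopulation"))
  st <- pop$truth$strains
  grp <- ifelse(is.na(st$event_id), "haploid", st$event_id)
  withSeed(seed, {
    prefH <- setNames(sample(habitats, length(unique(grp)), replace = TRUE),
                      unique(grp))
    prefC <- setNames(sample(continents, length(unique(grp)), replace = TRUE),
                      unique(grp))
    draw <- function(pref, all) {
      if (runif(1) < bias) pref else sample(setdiff(all, pref), 1)
    }
    data.frame(
      strain_id = st$strain_id,
      habitat = vapply(grp, function(g) draw(prefH[[g]], habitats), character(1)),
      location = vapply(grp, function(g) draw(prefC[[g]], continents), character(1)),
      ploidy = as.character(st$ploidy),
      stringsAsFactors = FALSE)
  })
}
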