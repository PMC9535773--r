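test_that("clonal haploid simulator matches its Poisson mutation oracle", {
  L <- 150000L
  # two lineages: all mutations are pairwise differences; target ~1000
  pop <- simulateClonalHaploids(2, L, divergence = 1000 / L, seed = 11)
  nDiff <- length(pop$usedSites)
  expect_gt(nDiff, 1000 - 4 * sqrt(1000))
  expect_lt(nDiff, 1000 + 4 * sqrt(1000))
  # mean pairwise divergence across a larger set tracks the tree scaling
  pop12 <- simulateClonalHaploids(12, L, divergence = 0.03, seed = 11)
  d <- ape::cophenetic.phylo(pop12$tree)
  expect_equal(mean(d[upper.tri(d)]), 0.03, tolerance = 1e-12)
})

test_that("clonal haploid simulator rejects bad inputs and is deterministic", {
  expect_error(simulateClonalHaploids(1, 1e5), "nLineages must be >= 2")
  expect_error(simulateClonalHaploids(8, 500, divergence = 0.9),
               "too small for requested divergence")
  a <- simulateClonalHaploids(5, 2e4, seed = 3)
  b <- simulateClonalHaploids(5, 2e4, seed = 3)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$ancestral, b$ancestral)
})

test_that("hybridization planting: counts, truth records, tetraploid, errors", {
  hap <- simulateClonalHaploids(12, 1e5, seed = 4)
  pop <- plantHybridizations(hap, 7, descendantsPerEvent = c(3L, 3L), seed = 4)
  pl <- vapply(pop$strains, `[[`, integer(1), "ploidy")
  expect_equal(sum(pl == 2), 21)          # 7 events x 3 descendants
  expect_equal(nrow(pop$truth$events), 7)
  # conservation: every diploid's event exists in the truth table
  ev <- pop$truth$strains$event_id[pop$truth$strains$ploidy == 2]
  expect_true(all(ev %in% pop$truth$events$event_id))

  none <- plantHybridizations(hap, 0, seed = 4)
  expect_equal(sum(vapply(none$strains, `[[`, integer(1), "ploidy") == 2), 0)
  expect_equal(nrow(none$truth$events), 0)

  tet <- plantHybridizations(hap, 3, descendantsPerEvent = c(2L, 2L),
                             tetraploid = c(1, 2), seed = 4)
  t1 <- tet$strains[["T1"]]
  expect_equal(t1$ploidy, 4L)
  expect_equal(names(t1$subgenomes), c("a", "b", "c", "d"))

  expect_error(plantHybridizations(hap, 1, pairs = matrix(c(3, 3), 2)),
               "identical lineages")
  expect_error(plantHybridizations(hap, 70), "exceeds the number")
})

test_that("Wright-Fisher clonal mode produces no mosaics (four-gamete test)", {
  gm <- simulateWrightFisher(50, 2e4, 2e-5, 0, 500, 20, seed = 21)
  expect_gt(nLoci(gm), 50)
  expect_equal(fourGameteViolations(dosage(gm)), 0L)
  # determinism
  gm2 <- simulateWrightFisher(50, 2e4, 2e-5, 0, 500, 20, seed = 21)
  expect_identical(dosage(gm), dosage(gm2))
  expect_identical(loci(gm), loci(gm2))
})

test_that("Wright-Fisher free recombination drives distant r2 to the 1/n floor", {
  n <- 30L
  gm <- simulateWrightFisher(100, 2e4, 3e-5, 1e-4, 400, n, seed = 22)
  pairs <- pairwiseR2(filterLdLoci(gm), maxDist = 20000L)
  far <- pairs$r2[pairs$distance > 5000]
  expect_gt(length(far), 200)
  # the finite-sample bias floor is ~1/n; allow broad Monte-Carlo slack
  expect_lt(mean(far), 3 / n)
})

test_that("depth simulator honours copy-number segments (NB moments oracle)", {
  cl <- c(ctg01 = 600000L)
  base <- simulateDepth(2L, cl, depthMean = 100, seed = 31)
  expect_equal(median(base$depth) / median(base$depth), 1)  # ratio 1 by construction
  tr <- windowDepth(base)
  expect_true(all(abs(mcols(tr)$ratio[!GenomicRanges::mcols(tr)$partial] - 1) < 0.1))

  seg <- data.frame(contig = "ctg01", start = 150000L, end = 300000L, copy = 3L)
  d3 <- simulateDepth(2L, cl, segments = seg, depthMean = 100,
                      dispersion = 10, resolution = 100L, seed = 31)
  inSeg <- d3$start >= 150000 & d3$end <= 300000
  # mean ratio ~ 1.5; NB sd per 100-bp bin at mu=150, size=10 is sqrt(150+2250)
  se <- sqrt(150 + 150^2 / 10) / sqrt(sum(inSeg)) / 100
  expect_lt(abs(mean(d3$depth[inSeg]) / 100 - 1.5), 4 * se)

  h2 <- simulateDepth(1L, cl, segments = transform(seg, copy = 2L),
                      depthMean = 100, seed = 32)
  se2 <- sqrt(200 + 200^2 / 10) / sqrt(sum(inSeg)) / 100
  expect_lt(abs(mean(h2$depth[inSeg]) / 100 - 2.0), 4 * se2)

  expect_error(simulateDepth(2L, cl, depthMean = 0), "depthMean must be > 0")
})

test_that("LOH planting removes heterozygosity and reports deletion depth", {
  set.seed(5)
  dos <- cbind(d1 = rep(1L, 60), h1 = rep(1L, 60))
  gm <- makeGm(dos, c(d1 = 2L, h1 = 1L), pos0 = seq(0, 59000, by = 1000))
  tracts <- data.frame(strain = "d1", contig = "c1", start = 0L, end = 40000L,
                       copy_neutral = TRUE)
  out <- plantLOH(gm, tracts, seed = 9)
  d <- dosage(out$genotypes)[, "d1"]
  inTract <- loci(gm)$pos0 < 40000
  expect_true(all(d[inTract] %in% c(0L, 2L)))          # 40 het sites collapsed
  expect_identical(d[!inTract], dos[!inTract, "d1"])   # outside untouched
  expect_equal(nrow(out$depthSegments), 0)

  del <- plantLOH(gm, transform(tracts, copy_neutral = FALSE), seed = 9)
  expect_equal(del$depthSegments$copy, 1L)
  expect_equal(del$depthSegments$end, 40000L)

  expect_identical(dosage(plantLOH(gm, NULL)$genotypes), dosage(gm))
  expect_error(plantLOH(gm, data.frame(strain = "h1", contig = "c1",
                                       start = 0L, end = 1000L,
                                       copy_neutral = TRUE)),
               "haploid strain")
})

test_that("assembly statistics draws match the per-ploidy distribution centres", {
  s1 <- simulateAssemblyStats(rep(1L, 1000), seed = 41)
  expect_lt(abs(mean(s1$assembly_size) - 26.52e6), 3 * 1.47e6 / sqrt(1000))
  s2 <- simulateAssemblyStats(rep(2L, 1000), seed = 42)
  expect_lt(abs(mean(s2$n_genes) - 20417), 3 * 1709 / sqrt(1000))
  s4 <- simulateAssemblyStats(rep(4L, 1000), seed = 43)
  expect_gte(mean(s4$assembly_size > 80e6), 0.99)
  expect_error(simulateAssemblyStats(3L), "unsupported ploidy")
})

test_that("metadata simulator biases habitats by event group", {
  hap <- simulateClonalHaploids(8, 5e4, seed = 6)
  pop <- plantHybridizations(hap, 3, descendantsPerEvent = c(4L, 4L), seed = 6)
  meta <- simulateMetadata(pop, bias = 1, seed = 6)
  expect_setequal(meta$strain_id, pop$truth$strains$strain_id)
  # with bias 1 all members of one event share one habitat
  for (e in pop$truth$events$event_id) {
    members <- pop$truth$strains$strain_id[pop$truth$strains$event_id %in% e]
    expect_equal(length(unique(meta$habitat[meta$strain_id %in% members])), 1)
  }
})
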