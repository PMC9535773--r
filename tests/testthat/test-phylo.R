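dna <- function(x) Biostrings::DNAStringSet(x)

test_that("region selection enforces ploidy match, gap fraction, and length rank", {
  pl <- c(s1 = 1L, s2 = 2L)
  good <- dna(c(s1 = "ACGTACGT", s2a = "ACGTACGA", s2b = "ACGAACGT"))
  missing <- good[c("s1", "s2a")]                 # diploid lost one subgenome
  gappy <- dna(c(s1 = "ACGTACGT", s2a = "AC--AC--", s2b = "ACGAACGT"))
  long <- dna(c(s1 = "ACGTACGTACGT", s2a = "ACGTACGTACGA",
                s2b = "ACGAACGTACGT"))
  alns <- list(r1 = good, r2 = missing, r3 = gappy, r4 = long)
  keep <- selectRegions(alns, pl, n = 2)
  expect_equal(names(keep), c("r4", "r1"))        # longest first, r2/r3 rejected
  expect_warning(selectRegions(alns, pl, n = 5), "only 2 regions")
})

test_that("neighbor joining recovers additive distances exactly", {
  # worked 4-leaf case: ((A:1,B:2):1,(C:3,D:4):1)
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr)
  nj <- ape::nj(D)
  expect_equal(phangorn::RF.dist(nj, ape::unroot(tr)), 0)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)

  # brute-force least-squares oracle over all topologies (5 and 6 leaves)
  for (n in c(5, 6)) {
    set.seed(n)
    true <- ape::rtree(n)
    true$edge.length <- runif(nrow(true$edge), 0.5, 2)
    D <- ape::cophenetic.phylo(true)
    best <- bruteForceLsTree(D)
    expect_lt(best$ss, 1e-16)                 # additive: exact fit exists
    nj <- ape::nj(D)
    expect_equal(phangorn::RF.dist(nj, best$tree), 0)
    expect_equal(max(abs(best$coph - D[rownames(best$coph),
                                       colnames(best$coph)])), 0,
                 tolerance = 1e-8)
  }
})

test_that("region trees from alignments recover the planted topology", {
  hap <- simulateClonalHaploids(6, 3e4, divergence = 0.05, seed = 17)
  alns <- regionAlignments(hap, nRegions = 3, regionLength = 10000)
  tr <- regionTree(alns[[1]])
  expect_setequal(tr$tip.label, sprintf("L%02d", 1:6))
  expect_equal(phangorn::RF.dist(tr, ape::unroot(hap$tree)), 0)
  expect_true(all(tr$edge.length >= 0))

  expect_error(regionTree(dna(c(a = "ACGT", b = "ACGT"))), ">= 3 sequences")
  # identical sequences: zero distances, zero branch lengths
  same <- regionTree(dna(c(a = "ACGT", b = "ACGT", c = "ACGT")))
  expect_equal(sum(same$edge.length), 0)
})

test_that("clade support counts and strict-majority consensus", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  same50 <- rep(list(t1), 50)
  cs <- cladeSupport(same50)
  expect_true(all(cs$support$support == 1))

  # trees are rooted at the reference leaf "a", so the (a,b)|(c,d,e) split of
  # t1 surfaces as the clade {c,d,e}; the (c,d) clade is t1-only as well
  mix <- c(rep(list(t1), 30), rep(list(t2), 20))
  cs <- cladeSupport(mix)
  expect_equal(cs$support$support[cs$support$clade == "c,d"], 0.6)
  expect_equal(cs$support$support[cs$support$clade == "b,d"], 0.4)

  # two clades each at exactly 0.5: neither enters the strict majority consensus
  half <- c(rep(list(t1), 2), rep(list(t2), 2))
  cons <- cladeSupport(half)$consensus
  expect_equal(cons$Nnode, 1)   # star: no internal structure survives

  t3 <- ape::read.tree(text = "((a,b),(c,f),e);")
  expect_error(cladeSupport(list(t1, t3)), "symmetric difference.*[df]")
})

test_that("concordance score spans identical to maximally conflicting trees", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(concordanceScore(list(t1, t1, t1)), 1)
  expect_equal(concordanceScore(list(t1, t2)), 0)
  expect_error(concordanceScore(list(t1)), ">= 2 trees")

  # clonal simulation: all regions share the planted genealogy
  hap <- simulateClonalHaploids(10, 1e5, divergence = 0.03, seed = 18)
  trees <- lapply(regionAlignments(hap, 20, 5000), regionTree)
  expect_gte(concordanceScore(trees), 0.8)
})

test_that("subgenome assignment recovers planted parental lineages", {
  hap <- simulateClonalHaploids(8, 1e5, divergence = 0.03, seed = 19)
  pop <- plantHybridizations(hap, 2, pairs = matrix(c(1, 5, 2, 7), 2),
                             descendantsPerEvent = c(3L, 3L),
                             tetraploid = c(1, 2), seed = 19)
  alns <- regionAlignments(pop, 20, 4000)
  D <- averageSubgenomeDistance(alns)
  asg <- assignSubgenomes(D)
  clusterOf <- function(lab) asg$lineage[asg$label == lab]
  # every haploid strain is assigned, and clusters carry haploid names
  expect_true(all(!asg$ambiguous[asg$strain == asg$label]))
  # diploid subgenomes land in the clusters of their two planted parents
  # (clusters are named after a haploid member, which may be a close sister
  # of the true parent; identity of cluster membership is what matters)
  d11 <- sort(asg$lineage[asg$strain == "D1.1"])
  expect_equal(d11, sort(c(clusterOf("L01"), clusterOf("L05"))))
  d21 <- sort(asg$lineage[asg$strain == "D2.1"])
  expect_equal(d21, sort(c(clusterOf("L02"), clusterOf("L07"))))
  # tetraploid: four assignments covering both parental pairs
  expect_equal(sort(asg$lineage[asg$strain == "T1"]),
               sort(c(clusterOf("L01"), clusterOf("L02"),
                      clusterOf("L05"), clusterOf("L07"))))

  ev <- inferHybridEvents(asg, D)
  expect_equal(nrow(ev$groups), 2)
  mem <- lapply(strsplit(ev$groups$members, ","), sort)
  expect_setequal(mem, list(paste0("D1.", 1:3), paste0("D2.", 1:3)))
  expect_equal(ev$tetraploids$strain, "T1")
})

test_that("event grouping: empty input and same-pair events with divergence", {
  hap <- simulateClonalHaploids(6, 1e5, divergence = 0.03, seed = 20)
  none <- plantHybridizations(hap, 0, seed = 20)
  alns <- regionAlignments(none, 10, 4000)
  D <- averageSubgenomeDistance(alns)
  asg <- assignSubgenomes(D)
  ev <- inferHybridEvents(asg, D, tauEvent = 0.002)
  expect_equal(nrow(ev$groups), 0)

  # two events on the same lineage pair, separated by founder-private drift
  pop <- plantHybridizations(hap, 2, pairs = matrix(c(1, 4, 1, 4), 2),
                             descendantsPerEvent = c(3L, 3L),
                             postDivergence = 2e-4,
                             founderDivergence = 5e-3, seed = 20)
  alns <- regionAlignments(pop, 20, 4000)
  D <- averageSubgenomeDistance(alns)
  asg <- assignSubgenomes(D)
  ev <- inferHybridEvents(asg, D, tauEvent = 0.002)
  expect_equal(nrow(ev$groups), 2)
  mem <- strsplit(ev$groups$members, ",")
  expect_true(all(vapply(mem, function(m)
    length(unique(sub("\\..*$", "", m))) == 1, logical(1))))
})

test_that("support, concordance and grouping are label-order invariant", {
  hap <- simulateClonalHaploids(6, 5e4, divergence = 0.03, seed = 23)
  pop <- plantHybridizations(hap, 2, descendantsPerEvent = c(2L, 2L), seed = 23)
  alns <- regionAlignments(pop, 10, 4000)
  D <- averageSubgenomeDistance(alns)
  perm <- sample(nrow(D))
  Dp <- D[perm, perm]
  ev1 <- inferHybridEvents(assignSubgenomes(D), D)
  ev2 <- inferHybridEvents(assignSubgenomes(Dp), Dp)
  expect_equal(nrow(ev1$groups), nrow(ev2$groups))
  expect_setequal(ev1$groups$members, ev2$groups$members)

  trees <- lapply(alns, regionTree)
  expect_equal(concordanceScore(trees), concordanceScore(rev(trees)))
  cs1 <- cladeSupport(trees)$support
  cs2 <- cladeSupport(rev(trees))$support
  expect_equal(cs1, cs2)
})
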