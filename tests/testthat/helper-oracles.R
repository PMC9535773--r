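# Independent oracles used across test files. These deliberately avoid the
# code paths they check.

# Classical haplotype-frequency r^2 for two phased haploid 0/1 vectors:
# r^2 = D^2 / (pA (1-pA) pB (1-pB)) with D = pAB - pA pB.
hapFormulaR2 <- function(x, y) {
  pA <- mean(x); pB <- mean(y); pAB <- mean(x & y)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Number of locus pairs violating the four-gamete test (all of 00,01,10,11
# present) in a phased haploid 0/1 matrix (loci x haplotypes). Under
# infinite sites with no recombination this must be zero.
fourGameteViolations <- function(m, maxPairs = 20000L) {
  n <- nrow(m)
  if (n < 2) return(0L)
  pairs <- combn(n, 2)
  if (ncol(pairs) > maxPairs) pairs <- pairs[, seq_len(maxPairs)]
  sum(vapply(seq_len(ncol(pairs)), function(k) {
    a <- m[pairs[1, k], ]; b <- m[pairs[2, k], ]
    length(unique(paste(a, b))) == 4
  }, logical(1)))
}

# Brute-force least-squares tree: enumerate every unrooted topology
# (phangorn::allTrees), fit branch lengths by ordinary least squares on the
# split design matrix (an edge contributes its length to exactly the tip
# pairs whose path crosses it), and return the topology with the smallest
# sum of squared residuals. Feasible up to ~6 leaves.
bruteForceLsTree <- function(D) {
  labs <- rownames(D)
  pairs <- t(combn(length(labs), 2))
  d <- D[pairs]
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  best <- NULL; bestSS <- Inf; bestCoph <- NULL
  for (i in seq_along(topos)) {
    tr <- topos[[i]]   # [[ reattaches the shared multiPhylo tip labels
    desc <- phangorn::Descendants(tr, tr$edge[, 2], "tips")
    A <- vapply(desc, function(tipSet) {
      inSet <- labs %in% tr$tip.label[tipSet]
      xor(inSet[pairs[, 1]], inSet[pairs[, 2]])
    }, logical(nrow(pairs))) * 1
    b <- qr.coef(qr(A), d)
    b[is.na(b)] <- 0
    fit <- as.vector(A %*% b)
    ss <- sum((fit - d)^2)
    if (ss < bestSS) {
      bestSS <- ss
      tr$edge.length <- b
      best <- tr
      coph <- matrix(0, length(labs), length(labs),
                     dimnames = list(labs, labs))
      coph[pairs] <- fit; coph[pairs[, 2:1]] <- fit
      bestCoph <- coph
    }
  }
  list(tree = best, coph = bestCoph, ss = bestSS)
}

# Random phased haploid GenotypeMatrix with given number of polymorphic loci.
randomHaploidGm <- function(nLoci, nHap, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nLoci * nHap, 1, runif(nLoci, 0.2, 0.8)), nLoci, nHap)
    mac <- pmin(rowSums(m), nHap - rowSums(m))
    if (all(mac >= 1)) break
  }
  GenotypeMatrix(
    data.frame(contig = "c1", pos0 = sort(sample.int(50000L, nLoci)) - 1L,
               ref = "A", alt = "C"),
    m, setNames(rep(1L, nHap), sprintf("h%02d", seq_len(nHap))))
}

# Small deterministic GenotypeMatrix builder.
makeGm <- function(dosage, ploidy, contig = "c1", pos0 = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(pos0)) pos0 <- seq_len(nrow(dosage)) * 10L
  GenotypeMatrix(
    data.frame(contig = contig, pos0 = as.integer(pos0), ref = "A", alt = "T"),
    dosage, ploidy)
}
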