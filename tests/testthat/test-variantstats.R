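test_that("SNP summaries: densities and heterozygous fractions", {
  # haploid with 400 alt loci in a 10 kbp genome -> 4% total, 0% het
  gmH <- makeGm(matrix(1L, 400, 1, dimnames = list(NULL, "h1")),
                c(h1 = 1L), pos0 = seq_len(400) * 10L)
  s <- snpSummaries(gmH, 1e4)
  expect_equal(s$total_snp_density, 0.04)
  expect_equal(s$het_snp_density, 0)

  # diploid: 100 dosage-1 + 50 dosage-2 loci -> 1.5% total, 1% het
  gmD <- makeGm(matrix(c(rep(1L, 100), rep(2L, 50)), ncol = 1,
                       dimnames = list(NULL, "d1")),
                c(d1 = 2L), pos0 = seq_len(150) * 10L)
  s <- snpSummaries(gmD, 1e4)
  expect_equal(s$total_snp_density, 0.015)
  expect_equal(s$het_snp_density, 0.010)
  expect_equal(s$het_fraction_of_snps, 100 / 150)

  # all-missing strain -> zero densities
  gmM <- makeGm(matrix(NA_integer_, 10, 1, dimnames = list(NULL, "m1")),
                c(m1 = 2L))
  expect_equal(snpSummaries(gmM, 1e4)$total_snp_density, 0)
})

test_that("pairwise dissimilarity matches brute-force mean absolute difference", {
  gm <- makeGm(cbind(a = c(0L, 0L, 0L, 0L), b = c(1L, 1L, 1L, 1L),
                     c = c(0L, 1L, 2L, NA)),
               c(a = 1L, b = 1L, c = 2L))
  D <- pairwiseDissimilarity(gm)
  expect_equal(D["a", "b"], 1)                     # all-ref vs all-alt haploids
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  # brute force on the co-typed loci of (a, c): |0-0|,|0-.5|,|0-1| over 3 loci
  expect_equal(D["a", "c"], mean(c(0, 0.5, 1)))
  expect_equal(D["b", "c"], mean(c(1, 0.5, 0)))

  dup <- makeGm(cbind(a = c(0L, 1L), a2 = c(0L, 1L)), c(a = 1L, a2 = 1L))
  expect_equal(pairwiseDissimilarity(dup)["a", "a2"], 0)
})

test_that("dissimilarity satisfies the triangle inequality on co-typed data", {
  set.seed(12)
  dos <- matrix(sample(0:2, 30 * 6, replace = TRUE), 30, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  gm <- makeGm(dos, setNames(rep(2L, 6), paste0("s", 1:6)))
  D <- pairwiseDissimilarity(gm)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("PCA separates clusters and reconstructs the centred matrix", {
  dos <- cbind(a1 = rep(0L, 20), a2 = rep(0L, 20),
               b1 = rep(1L, 20), b2 = rep(1L, 20))
  dos[1, ] <- c(0L, 0L, 1L, 0L)   # one variable locus beyond the split
  gm <- makeGm(dos, setNames(rep(1L, 4), colnames(dos)))
  pc <- genotypePca(gm, 2)
  expect_gt(pc$varianceExplained[1], 0.9)
  expect_lt(abs(pc$scores["a1", 1] - pc$scores["a2", 1]), 1e-9)

  # full-rank reconstruction oracle on a random matrix
  set.seed(13)
  dos <- matrix(sample(0:1, 40 * 8, replace = TRUE), 40, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
  gm <- makeGm(dos, setNames(rep(1L, 8), paste0("s", 1:8)))
  f <- dosage(gm)
  keep <- apply(f, 1, function(x) var(x) > 0)
  x <- t(f[keep, ])
  pc <- prcomp(x, center = TRUE)
  rec <- pc$x %*% t(pc$rotation) + matrix(colMeans(x), nrow(x), ncol(x),
                                          byrow = TRUE)
  expect_lt(max(abs(rec - x)), 1e-8)
  # variance shares sum to 1 and are non-increasing
  all <- genotypePca(gm, 2)$allVariance
  expect_equal(sum(all), 1)
  expect_true(all(diff(all) <= 1e-12))

  expect_error(genotypePca(gm, 10), "exceeds")
})

test_that("PCA variance explained is invariant to locus and strain order", {
  set.seed(14)
  dos <- matrix(sample(0:2, 50 * 7, replace = TRUE), 50, 7,
                dimnames = list(NULL, paste0("s", 1:7)))
  gm <- makeGm(dos, setNames(rep(2L, 7), paste0("s", 1:7)))
  v1 <- genotypePca(gm, 3)$varianceExplained
  perm <- sample(50); sperm <- sample(7)
  gm2 <- makeGm(dos[perm, sperm][order(perm), ],
                setNames(rep(2L, 7), paste0("s", 1:7)[sperm]))
  # locus order within the matrix is tied to positions; shuffling strains only
  gm3 <- gm[, sperm]
  v3 <- genotypePca(gm3, 3)$varianceExplained
  expect_equal(v1, v3, tolerance = 1e-10)
})
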