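# Per-strain SNP summaries, pairwise dissimilarity, and PCA of the genotype
# matrix. Dosages are placed on a per-allele-frequency scale (dosage/ploidy)
# so haploid and diploid strains are comparable on one axis.

#' Per-strain SNP density summaries
#'
#' Total SNP density is the fraction of the genome at which a strain carries
#' at least one non-reference allele; heterozygous SNP density is the
#' fraction at which it carries both alleles (0 < dosage < ploidy). Matches
#' the "SNPs per total genome size" convention.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param genomeLength Genome length in bp (> 0).
#' @return data.frame `strain_id, n_snp, n_het, total_snp_density,
#'   het_snp_density, het_fraction_of_snps`.
#' @export
snpSummaries <- function(gm, genomeLength) {
  if (genomeLength <= 0) stop("genomeLength must be > 0")
  dos <- dosage(gm)
  pl <- strainPloidy(gm)
  nSnp <- colSums(dos > 0L, na.rm = TRUE)
  nHet <- vapply(seq_along(pl), function(j) {
    d <- dos[, j]
    sum(!is.na(d) & d > 0L & d < pl[j])
  }, numeric(1))
  data.frame(strain_id = names(pl),
             n_snp = as.integer(nSnp), n_het = as.integer(nHet),
             total_snp_density = nSnp / genomeLength,
             het_snp_density = nHet / genomeLength,
             het_fraction_of_snps = ifelse(nSnp > 0, nHet / nSnp, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise strain dissimilarity
#'
#' Mean absolute difference of ploidy-normalized dosages over loci typed in
#' both strains: `d(i, j) = mean |dos_i/p_i - dos_j/p_j|`. Identical strains
#' have distance 0; a haploid all-reference vs all-alternate pair has
#' distance 1. Pairs with no co-typed loci get `NA` (reported, not dropped).
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Symmetric numeric matrix of dissimilarities with zero diagonal.
#' @export
pairwiseDissimilarity <- function(gm) {
  pl <- strainPloidy(gm)
  f <- sweep(dosage(gm), 2, pl, "/")      # per-allele frequency scale
  n <- length(pl)
  D <- matrix(0, n, n, dimnames = list(names(pl), names(pl)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ok <- !is.na(f[, i]) & !is.na(f[, j])
    D[i, j] <- D[j, i] <- if (any(ok)) mean(abs(f[ok, i] - f[ok, j])) else NA_real_
  }
  D
}

#' Principal component analysis of the genotype matrix
#'
#' Dosages are scaled to per-allele frequencies (dosage/ploidy), missing
#' values are mean-imputed per locus, invariant loci are dropped, and the
#' strain scores come from the eigendecomposition of the column-centred
#' matrix (via [stats::prcomp()]). Variance-explained fractions are
#' eigenvalue shares over all components.
#'
#' @param gm A [GenotypeMatrix-class] with >= 2 strains and >= 2 variable loci.
#' @param nComponents Number of components to retain (<= min(strains - 1,
#'   loci)).
#' @return list with `scores` (strains x components), `varianceExplained`
#'   (per retained component), and `allVariance` (shares over all
#'   components, summing to 1).
#' @export
genotypePca <- function(gm, nComponents = 2L) {
  pl <- strainPloidy(gm)
  if (length(pl) < 2) stop("need >= 2 strains")
  f <- sweep(dosage(gm), 2, pl, "/")
  mu <- rowMeans(f, na.rm = TRUE)
  for (i in which(apply(is.na(f), 1, any))) f[i, is.na(f[i, ])] <- mu[i]
  keep <- apply(f, 1, function(x) stats::var(x) > 0)
  f <- f[keep, , drop = FALSE]
  if (nrow(f) < 2) stop("need >= 2 variable loci after dropping invariants")
  maxComp <- min(length(pl) - 1L, nrow(f))
  if (nComponents > maxComp)
    stop("nComponents exceeds min(strains - 1, loci) = ", maxComp)
  pc <- prcomp(t(f), center = TRUE, scale. = FALSE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       varianceExplained = shares[seq_len(nComponents)],
       allVariance = shares)
}
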