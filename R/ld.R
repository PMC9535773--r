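# Linkage-disequilibrium decay: pairwise r^2 for nearby biallelic
# non-singleton loci, the distance-binned decay curve with a local
# tricube-weighted smoother, and the half-maximum decay readout. In a clonal
# population all loci share one genealogy, so r^2 does not decay with
# distance; under recombination the smoothed curve crosses half of its
# maximum at a finite distance.

#' Filter loci for LD analysis
#'
#' Keeps loci that are biallelic and non-singleton: the minor allele must be
#' carried by at least 2 strains.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return The filtered `GenotypeMatrix`.
#' @export
filterLdLoci <- function(gm) {
  dos <- dosage(gm)
  pl <- strainPloidy(gm)
  altCarriers <- rowSums(dos > 0L, na.rm = TRUE)
  refCarriers <- rowSums(sweep(dos, 2, pl, "<"), na.rm = TRUE)
  keep <- loci(gm)$biallelic & pmin(altCarriers, refCarriers) >= 2L
  gm[keep, ]
}

#' Pairwise r-squared between nearby loci
#'
#' For every same-contig pair of loci at distance 1..`maxDist`, r^2 is the
#' squared Pearson correlation of the ploidy-scaled dosage vectors over
#' strains typed at both loci (the genotype-correlation estimator; on phased
#' haploid data it equals the classical haplotype-frequency formula
#' `D^2 / (pA(1-pA) pB(1-pB))` exactly). Pairs where either locus has zero
#' variance among co-typed strains are skipped.
#'
#' @param gm A [GenotypeMatrix-class], already passed through
#'   [filterLdLoci()].
#' @param maxDist Maximum inter-locus distance in bp (default 10,000).
#' @return data.frame `contig, distance, r2`.
#' @export
pairwiseR2 <- function(gm, maxDist = 10000L) {
  lo <- loci(gm)
  f <- sweep(dosage(gm), 2, strainPloidy(gm), "/")
  out <- lapply(unique(lo$contig), function(ct) {
    idx <- which(lo$contig == ct)
    if (length(idx) < 2) return(NULL)
    pos <- lo$pos0[idx]
    m <- t(f[idx, , drop = FALSE])       # strains x loci
    # block the loci so the correlation matrix stays modest for dense contigs
    blockSize <- 2000L
    starts <- seq(1L, length(idx), by = blockSize)
    res <- list()
    for (bs in starts) {
      be <- min(bs + blockSize - 1L, length(idx))
      # partner loci: everything in the block plus loci within maxDist ahead
      pe <- be
      while (pe < length(idx) && pos[pe + 1L] - pos[be] <= maxDist) pe <- pe + 1L
      cols <- seq.int(bs, pe)
      cc <- suppressWarnings(cor(m[, cols, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      nb <- be - bs + 1L
      pr <- which(upper.tri(cc), arr.ind = TRUE)
      pr <- pr[pr[, 1] <= nb, , drop = FALSE]   # left locus inside the block
      d <- pos[cols[pr[, 2]]] - pos[cols[pr[, 1]]]
      ok <- d > 0 & d <= maxDist & !is.na(cc[pr])
      if (any(ok))
        res[[length(res) + 1L]] <- data.frame(
          contig = ct, distance = d[ok], r2 = cc[pr][ok]^2)
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(0), distance = integer(0),
                      r2 = numeric(0))
  rownames(out) <- NULL
  out
}

#' Distance-binned LD decay curve with half-maximum readout
#'
#' Bins the r^2 values by inter-locus distance, smooths the bin means with a
#' pair-count-weighted tricube local mean, and reads off the half-maximum
#' decay distance: the smallest bin midpoint at which the smoothed curve
#' falls below half of its maximum (`NA` when never reached — the clonal
#' signature).
#'
#' @param pairs data.frame from [pairwiseR2()].
#' @param maxDist Upper end of the distance range (bp).
#' @param binWidth Bin width in bp (default 100).
#' @param smootherSpan Span of the tricube smoother as a fraction of the
#'   distance range (default 0.2).
#' @return list of class `LDCurve`: `bins` (data.frame `mid, n_pairs,
#'   mean_r2, smoothed_r2`), `maxObserved` (max of the smoothed curve),
#'   `halfMax`, `halfDecayDistance` (bp, `NA` = not reached).
#' @export
ldCurve <- function(pairs, maxDist = 10000L, binWidth = 100L,
                    smootherSpan = 0.2) {
  if (nrow(pairs) == 0) stop("insufficient LD pairs")
  edges <- seq(0L, maxDist, by = binWidth)
  if (tail(edges, 1) < maxDist) edges <- c(edges, maxDist)
  bin <- cut(pairs$distance, edges, right = TRUE, labels = FALSE)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  n <- tabulate(bin, nbins = length(mids))
  sums <- vapply(seq_along(mids), function(b) sum(pairs$r2[bin == b]), numeric(1))
  meanR2 <- ifelse(n > 0, sums / pmax(n, 1), NA_real_)
  occ <- which(n > 0)
  span <- smootherSpan * (maxDist - 0)
  smoothed <- rep(NA_real_, length(mids))
  for (b in occ) {
    u <- abs(mids[occ] - mids[b]) / span
    w <- ifelse(u < 1, (1 - u^3)^3, 0) * n[occ]
    smoothed[b] <- sum(w * meanR2[occ]) / sum(w)
  }
  maxObs <- max(smoothed, na.rm = TRUE)
  halfMax <- maxObs / 2
  below <- occ[smoothed[occ] < halfMax]
  halfDecay <- if (length(below)) mids[min(below)] else NA_real_
  structure(list(bins = data.frame(mid = mids, n_pairs = n, mean_r2 = meanR2,
                                   smoothed_r2 = smoothed),
                 maxObserved = maxObs, halfMax = halfMax,
                 halfDecayDistance = halfDecay),
            class = "LDCurve")
}

#' @export
print.LDCurve <- function(x, ...) {
  cat(sprintf("LDCurve: max smoothed r2 = %.4f, half = %.4f, half-decay = %s\n",
              x$maxObserved, x$halfMax,
              if (is.na(x$halfDecayDistance)) "not reached"
              else paste0(x$halfDecayDistance, " bp")))
  invisible(x)
}

#' One-call LD decay analysis
#'
#' Convenience wrapper: [filterLdLoci()] then [pairwiseR2()] then
#' [ldCurve()].
#'
#' @inheritParams pairwiseR2
#' @inheritParams ldCurve
#' @return An `LDCurve` (see [ldCurve()]).
#' @export
ldDecay <- function(gm, maxDist = 10000L, binWidth = 100L,
                    smootherSpan = 0.2) {
  ldCurve(pairwiseR2(filterLdLoci(gm), maxDist = maxDist),
          maxDist = maxDist, binWidth = binWidth,
          smootherSpan = smootherSpan)
}
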