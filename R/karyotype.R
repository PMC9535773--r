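# Aneuploidy from median-normalized depth windows and LOH from
# heterozygosity windows. Depth windows default to 30 kbp, heterozygosity
# windows to 25 kbp; a window's statistic is its median depth divided by the
# genome-wide median, so the baseline copy number maps to ratio 1 and a
# trisomic segment of a diploid to ratio 1.5.

#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width
#' @importFrom IRanges IRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Combine per-contig GRanges; harmonizes seqlevels first so c() stays quiet.
bindRanges <- function(grl) {
  lev <- unique(unlist(lapply(grl, function(g) GenomeInfoDb::seqlevels(g))))
  grl <- lapply(grl, function(g) { GenomeInfoDb::seqlevels(g) <- lev; g })
  do.call(c, grl)
}

tileContig <- function(contig, len, windowSize) {
  starts <- seq.int(0L, len - 1L, by = windowSize)
  ends <- pmin(starts + windowSize, len)
  GRanges(contig, IRanges(starts + 1L, ends))   # GRanges is 1-based closed
}

#' Median-normalized depth windows
#'
#' Aggregates a raw depth track into fixed windows (default 30 kbp): the
#' window statistic (median by default, mean optionally) of the raw values,
#' divided by the genome-wide median of the raw values. Trailing partial
#' windows are flagged and excluded from segment calling.
#'
#' @param raw data.frame `contig, start, end, depth` (0-based half-open,
#'   regular fine bins), e.g. from [simulateDepth()] or [readDepthTsv()].
#' @param windowSize Window size in bp (default 30,000).
#' @param stat `"median"` (robust, default) or `"mean"`.
#' @return A [GenomicRanges::GRanges] with metadata columns `ratio`, `n`
#'   (raw bins aggregated), and `partial`.
#' @export
windowDepth <- function(raw, windowSize = 30000L, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  agg <- if (stat == "median") median else mean
  gmed <- median(raw$depth)
  if (gmed <= 0) stop("genome-wide median depth is zero; track unusable")
  out <- lapply(unique(raw$contig), function(ct) {
    d <- raw[raw$contig == ct, ]
    len <- max(d$end)
    win <- tileContig(ct, len, windowSize)
    wi <- windowIndex(d$start, windowSize) + 1L
    ratio <- vapply(seq_along(win), function(w) {
      v <- d$depth[wi == w]
      if (length(v)) agg(v) / gmed else NA_real_
    }, numeric(1))
    mcols(win)$ratio <- ratio
    mcols(win)$n <- tabulate(wi, nbins = length(win))
    mcols(win)$partial <- width(win) < windowSize
    win
  })
  bindRanges(out)
}

#' Call aneuploid segments from a depth track
#'
#' Each complete window is assigned to the nearest copy-state band
#' `k / baselinePloidy` (k = 1 .. 2 x baseline) when its ratio lies within
#' `bandTolerance` of the band, and maximal runs of at least `minRun`
#' consecutive windows in one non-baseline band become segments — the
#' published visual procedure (windows clustering on the haploid or triploid
#' expectation lines of an otherwise diploid genome) made explicit.
#'
#' @param track `GRanges` from [windowDepth()].
#' @param baselinePloidy Baseline ploidy (1, 2 or 4).
#' @param bandTolerance Half-width of a band in ratio units (default 0.15).
#' @param minRun Minimum run length in windows (default 5, i.e. 150 kbp of
#'   30-kbp windows).
#' @return `GRanges` of segments with metadata `copy_state`, `mean_ratio`,
#'   `n_windows`.
#' @export
callAneuploidSegments <- function(track, baselinePloidy,
                                  bandTolerance = 0.15, minRun = 5L) {
  if (!baselinePloidy %in% c(1L, 2L, 4L))
    stop("baselinePloidy must be 1, 2 or 4")
  bands <- seq_len(2L * baselinePloidy) / baselinePloidy
  segs <- list()
  for (ct in unique(as.character(seqnames(track)))) {
    win <- track[seqnames(track) == ct]
    ratio <- mcols(win)$ratio
    usable <- !mcols(win)$partial & !is.na(ratio)
    k <- vapply(ratio, function(x) {
      if (is.na(x)) return(NA_integer_)
      i <- which.min(abs(bands - x))
      if (abs(bands[i] - x) <= bandTolerance) i else NA_integer_
    }, integer(1))
    k[!usable] <- NA_integer_
    for (state in setdiff(unique(k[!is.na(k)]), baselinePloidy)) {
      flag <- !is.na(k) & k == state
      for (run in runsAtLeast(flag, minRun)) {
        idx <- seq.int(run[1], run[2])
        segs[[length(segs) + 1L]] <- GRanges(
          ct, IRanges(min(start(win)[idx]), max(end(win)[idx])),
          copy_state = as.integer(state),
          mean_ratio = mean(ratio[idx]),
          n_windows = length(idx))
      }
    }
  }
  if (!length(segs))
    return(GRanges(copy_state = integer(0), mean_ratio = numeric(0),
                   n_windows = integer(0)))
  sort(bindRanges(segs))
}

#' Heterozygosity windows for one strain
#'
#' Counts heterozygous loci (0 < dosage < ploidy) of the strain in fixed
#' windows (default 25 kbp) and normalizes by the genome-wide median window
#' count, mirroring the depth-window construction on the heterozygosity
#' axis.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param strain Strain id (must have ploidy >= 2).
#' @param contigLengths Named integer vector of contig lengths; defaults to
#'   the last locus position per contig rounded up to a whole window.
#' @param windowSize Window size in bp (default 25,000).
#' @return `GRanges` with metadata `het_count`, `ratio`, `partial`.
#' @export
windowHeterozygosity <- function(gm, strain, contigLengths = NULL,
                                 windowSize = 25000L) {
  pl <- strainPloidy(gm)
  if (!strain %in% names(pl)) stop("unknown strain ", strain)
  p <- pl[[strain]]
  if (p < 2) stop("strain ", strain, " is haploid; heterozygosity undefined")
  lo <- loci(gm)
  d <- dosage(gm)[, strain]
  het <- !is.na(d) & d > 0L & d < p
  if (is.null(contigLengths)) {
    contigLengths <- vapply(split(lo$pos0, lo$contig), function(p0)
      as.integer(ceiling((max(p0) + 1) / windowSize) * windowSize), integer(1))
  }
  out <- lapply(names(contigLengths), function(ct) {
    win <- tileContig(ct, contigLengths[[ct]], windowSize)
    sel <- lo$contig == ct
    counts <- tabulate(windowIndex(lo$pos0[sel][het[sel]], windowSize) + 1L,
                       nbins = length(win))
    mcols(win)$het_count <- counts
    mcols(win)$partial <- width(win) < windowSize
    win
  })
  track <- bindRanges(out)
  med <- median(mcols(track)$het_count[!mcols(track)$partial])
  if (is.na(med) || med == 0)
    stop("median heterozygous-window count is zero: ",
         "insufficient heterozygosity for LOH analysis")
  mcols(track)$ratio <- mcols(track)$het_count / med
  track
}

# Interval-weighted mean of a depth track's ratios over a target grid.
resampleRatio <- function(track, grid) {
  hits <- findOverlaps(grid, track)
  ov <- width(pintersect(grid[queryHits(hits)], track[subjectHits(hits)]))
  r <- mcols(track)$ratio[subjectHits(hits)]
  ok <- !is.na(r)
  num <- tapply(ov[ok] * r[ok], queryHits(hits)[ok], sum)
  den <- tapply(ov[ok], queryHits(hits)[ok], sum)
  out <- rep(NA_real_, length(grid))
  out[as.integer(names(num))] <- num / den
  out
}

#' Call loss-of-heterozygosity segments
#'
#' Runs of at least `minRun` complete windows whose heterozygosity ratio is
#' below `hetThreshold` become LOH segments. The depth track (native 30-kbp
#' grid) is resampled onto the heterozygosity grid by interval-weighted
#' mean, and the segment's mean depth ratio classifies it: within
#' `bandTolerance` of 0.5 = `deletion` (one copy lost), within
#' `bandTolerance` of 1.0 = `copy_neutral` (mitotic recombination), anything
#' else = `ambiguous`.
#'
#' @param het `GRanges` from [windowHeterozygosity()].
#' @param depth `GRanges` from [windowDepth()] for the same strain.
#' @param hetThreshold LOH threshold as fraction of the median window
#'   heterozygosity (default 0.1).
#' @param bandTolerance Depth-band half-width (default 0.15).
#' @param minRun Minimum run length in windows (default 5).
#' @return `GRanges` of segments with metadata `class`, `mean_het_ratio`,
#'   `mean_depth_ratio`, `n_windows`.
#' @export
callLohSegments <- function(het, depth, hetThreshold = 0.1,
                            bandTolerance = 0.15, minRun = 5L) {
  depthOnGrid <- resampleRatio(depth, het)
  segs <- list()
  for (ct in unique(as.character(seqnames(het)))) {
    sel <- as.character(seqnames(het)) == ct
    win <- het[sel]
    hr <- mcols(win)$ratio
    dr <- depthOnGrid[sel]
    flag <- !mcols(win)$partial & !is.na(hr) & hr < hetThreshold
    for (run in runsAtLeast(flag, minRun)) {
      idx <- seq.int(run[1], run[2])
      mdr <- mean(dr[idx], na.rm = TRUE)
      cls <- if (!is.na(mdr) && abs(mdr - 0.5) <= bandTolerance) "deletion"
             else if (!is.na(mdr) && abs(mdr - 1.0) <= bandTolerance) "copy_neutral"
             else "ambiguous"
      segs[[length(segs) + 1L]] <- GRanges(
        ct, IRanges(min(start(win)[idx]), max(end(win)[idx])),
        class = cls, mean_het_ratio = mean(hr[idx]),
        mean_depth_ratio = mdr, n_windows = length(idx))
    }
  }
  if (!length(segs))
    return(GRanges(class = character(0), mean_het_ratio = numeric(0),
                   mean_depth_ratio = numeric(0), n_windows = integer(0)))
  sort(bindRanges(segs))
}

#' Write called segments as BED
#'
#' BED4+1: contig, 0-based start, end, name (copy state or LOH class),
#' score (mean ratio x 1000, rounded).
#'
#' @param segments `GRanges` from [callAneuploidSegments()] or
#'   [callLohSegments()].
#' @param path Output path.
#' @export
writeSegmentsBed <- function(segments, path) {
  mc <- mcols(segments)
  name <- if ("copy_state" %in% names(mc)) paste0("copy", mc$copy_state)
          else as.character(mc$class)
  ratio <- if ("mean_ratio" %in% names(mc)) mc$mean_ratio else mc$mean_depth_ratio
  df <- data.frame(as.character(seqnames(segments)), start(segments) - 1L,
                   end(segments), name, round(ratio * 1000))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
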