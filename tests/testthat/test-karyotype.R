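suppressMessages(library(GenomicRanges))

constantDepth <- function(len, depth, contig = "c1", res = 100L) {
  starts <- seq.int(0L, len - 1L, by = res)
  data.frame(contig = contig, start = starts, end = pmin(starts + res, len),
             depth = depth)
}

test_that("depth windows normalize to the genome-wide median", {
  raw <- constantDepth(300000L, 100)
  tr <- windowDepth(raw)
  expect_true(all(mcols(tr)$ratio == 1))

  # one contig at depth 150 in an otherwise depth-100 genome -> ratio 1.5
  raw2 <- rbind(constantDepth(600000L, 100, "big"),
                constantDepth(90000L, 150, "hot"))
  tr2 <- windowDepth(raw2)
  hot <- tr2[seqnames(tr2) == "hot"]
  expect_true(all(mcols(hot)$ratio == 1.5))

  expect_error(windowDepth(constantDepth(60000L, 0)), "median depth is zero")
})

test_that("aneuploid segment calling: bands, run length, and boundaries", {
  mk <- function(ratios) {
    win <- GenomicRanges::tileGenome(c(c1 = length(ratios) * 30000L),
                                     tilewidth = 30000L,
                                     cut.last.tile.in.chrom = TRUE)
    mcols(win)$ratio <- ratios
    mcols(win)$partial <- FALSE
    win
  }
  expect_length(callAneuploidSegments(mk(rep(1, 30)), 2L), 0)

  ratios <- rep(1, 30); ratios[11:20] <- 1.5
  segs <- callAneuploidSegments(mk(ratios), 2L)
  expect_length(segs, 1)
  expect_equal(mcols(segs)$copy_state, 3L)
  expect_equal(start(segs), 10 * 30000 + 1)
  expect_equal(end(segs), 20 * 30000)

  short <- rep(1, 30); short[5:7] <- 1.5
  expect_length(callAneuploidSegments(mk(short), 2L), 0)

  # monosomy band in a diploid
  mono <- rep(1, 30); mono[3:9] <- 0.5
  m <- callAneuploidSegments(mk(mono), 2L)
  expect_equal(mcols(m)$copy_state, 1L)
})

test_that("heterozygosity windows flag planted LOH and reject haploids", {
  set.seed(3)
  nl <- 2000L
  pos <- sort(sample.int(500000L, nl)) - 1L
  dos <- cbind(d1 = rep(1L, nl), h1 = rep(1L, nl))
  gm <- makeGm(dos, c(d1 = 2L, h1 = 1L), pos0 = pos)
  het <- windowHeterozygosity(gm, "d1", contigLengths = c(c1 = 500000L))
  expect_true(all(abs(mcols(het)$ratio - 1) < 1))   # uniform-ish

  out <- plantLOH(gm, data.frame(strain = "d1", contig = "c1",
                                 start = 100000L, end = 200000L,
                                 copy_neutral = TRUE), seed = 1)
  het2 <- windowHeterozygosity(out$genotypes, "d1",
                               contigLengths = c(c1 = 500000L))
  inTract <- start(het2) > 100000 & end(het2) <= 200000
  expect_true(all(mcols(het2)$ratio[inTract] == 0))

  expect_error(windowHeterozygosity(gm, "h1"), "haploid")
})

test_that("LOH segments classify copy-neutral vs deletion via depth", {
  set.seed(4)
  nl <- 3000L
  pos <- sort(sample.int(750000L, nl)) - 1L
  gm <- makeGm(cbind(d1 = rep(1L, nl)), c(d1 = 2L), pos0 = pos)
  tracts <- data.frame(strain = "d1", contig = "c1",
                       start = c(125000L, 500000L), end = c(300000L, 675000L),
                       copy_neutral = c(TRUE, FALSE))
  out <- plantLOH(gm, tracts, seed = 2)
  depthRaw <- simulateDepth(2L, c(c1 = 750000L),
                            segments = out$depthSegments[, c("contig", "start",
                                                             "end", "copy")],
                            depthMean = 100, seed = 2)
  depth <- windowDepth(depthRaw)
  het <- windowHeterozygosity(out$genotypes, "d1",
                              contigLengths = c(c1 = 750000L))
  segs <- callLohSegments(het, depth)
  expect_length(segs, 2)
  expect_equal(mcols(segs)$class, c("copy_neutral", "deletion"))
  # breakpoints within one 25-kbp window of the planted tracts
  expect_lt(abs(start(segs)[1] - 125001), 25000)
  expect_lt(abs(end(segs)[1] - 300000), 25000)

  # no low-heterozygosity runs -> empty result
  het0 <- windowHeterozygosity(gm, "d1", contigLengths = c(c1 = 750000L))
  expect_length(callLohSegments(het0, depth), 0)
})

test_that("segment BED export writes 0-based half-open records", {
  seg <- GRanges("c1", IRanges(30001, 60000), copy_state = 3L,
                 mean_ratio = 1.5, n_windows = 1L)
  f <- tempfile(fileext = ".bed")
  writeSegmentsBed(seg, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 30000)
  expect_equal(bed$V3, 60000)
  expect_equal(bed$V4, "copy3")
})
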