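#' @import methods
#' @importFrom stats median cor prcomp rpois rnorm rbinom rnbinom runif dhyper r2dtable setNames complete.cases
#' @importFrom utils read.delim write.table head tail combn
NULL

#' GenotypeMatrix: loci-by-strains allele dosages
#'
#' The central container of the package: a matrix of alternate-allele dosages
#' (rows are loci, columns are strains) together with locus coordinates and a
#' per-strain ploidy. A dosage of `d` at a locus in a strain of ploidy `p`
#' means `d` of the `p` genome copies carry the alternate allele; `0 < d < p`
#' is a heterozygous site. Positions are stored 0-based; converters to and
#' from 1-based VCF coordinates live in the IO layer.
#'
#' @slot loci data.frame with columns `contig` (character), `pos0` (0-based
#'   integer position), `ref`, `alt` (comma-separated when multiallelic) and
#'   `biallelic` (logical: exactly one alternate allele).
#' @slot dosage integer matrix, `nrow(loci)` x `length(ploidy)`; `NA` encodes
#'   a missing genotype.
#' @slot ploidy named integer vector of per-strain ploidies; names are the
#'   strain identifiers and double as `colnames(dosage)`.
#'
#' @export
setClass("GenotypeMatrix",
  representation(loci = "data.frame", dosage = "matrix", ploidy = "integer"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  lo <- object@loci
  need <- c("contig", "pos0", "ref", "alt", "biallelic")
  if (!all(need %in% names(lo)))
    msg <- c(msg, paste("loci must have columns", paste(need, collapse = ", ")))
  if (nrow(lo) != nrow(object@dosage))
    msg <- c(msg, "nrow(loci) must equal nrow(dosage)")
  if (length(object@ploidy) != ncol(object@dosage))
    msg <- c(msg, "length(ploidy) must equal ncol(dosage)")
  if (is.null(names(object@ploidy)) || anyDuplicated(names(object@ploidy)))
    msg <- c(msg, "ploidy must be named with unique strain ids")
  if (all(need %in% names(lo)) && nrow(lo) > 1) {
    bad <- unlist(tapply(lo$pos0, lo$contig, function(p) any(diff(p) <= 0)))
    if (any(bad))
      msg <- c(msg, paste0("positions must be strictly increasing within contig(s): ",
                           paste(names(bad)[bad], collapse = ", ")))
  }
  if (length(object@ploidy) == ncol(object@dosage) && ncol(object@dosage) > 0) {
    pl <- rep(object@ploidy, each = nrow(object@dosage))
    d <- as.vector(object@dosage)
    bad <- !is.na(d) & (d < 0 | d > pl)
    if (any(bad)) msg <- c(msg, "dosage values must lie in 0..ploidy or be NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param loci data.frame with columns `contig`, `pos0`, `ref`, `alt`
#'   (`biallelic` is derived from `alt` when absent).
#' @param dosage numeric/integer matrix, loci x strains.
#' @param ploidy named integer vector of per-strain ploidy, or an unnamed
#'   vector if `dosage` has column names.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' loci <- data.frame(contig = "c1", pos0 = c(0L, 10L), ref = "A", alt = "T")
#' gm <- GenotypeMatrix(loci, matrix(c(0L, 1L, 2L, 2L), 2), c(s1 = 2L, s2 = 2L))
#' dosage(gm)
#' @export
GenotypeMatrix <- function(loci, dosage, ploidy) {
  loci <- as.data.frame(loci)
  if (is.null(loci$biallelic))
    loci$biallelic <- !grepl(",", loci$alt) & nzchar(loci$alt)
  loci$contig <- as.character(loci$contig)
  loci$pos0 <- as.integer(loci$pos0)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(names(ploidy)) && !is.null(colnames(dosage)))
    names(ploidy) <- colnames(dosage)
  ploidy <- setNames(as.integer(ploidy), names(ploidy))
  colnames(dosage) <- names(ploidy)
  rownames(loci) <- NULL
  new("GenotypeMatrix", loci = loci, dosage = dosage, ploidy = ploidy)
}

#' @describeIn GenotypeMatrix-class Dosage matrix (loci x strains).
#' @param x,object A `GenotypeMatrix`.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn GenotypeMatrix-class Locus table.
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))
#' @export
setMethod("loci", "GenotypeMatrix", function(x) x@loci)

#' @describeIn GenotypeMatrix-class Named per-strain ploidy vector.
#' @export
setGeneric("strainPloidy", function(x) standardGeneric("strainPloidy"))
#' @export
setMethod("strainPloidy", "GenotypeMatrix", function(x) x@ploidy)

#' @describeIn GenotypeMatrix-class Strain identifiers.
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @export
setMethod("strainNames", "GenotypeMatrix", function(x) names(x@ploidy))

#' @describeIn GenotypeMatrix-class Number of loci.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @export
setMethod("nLoci", "GenotypeMatrix", function(x) nrow(x@loci))

#' @describeIn GenotypeMatrix-class Number of strains.
#' @export
setGeneric("nStrains", function(x) standardGeneric("nStrains"))
#' @export
setMethod("nStrains", "GenotypeMatrix", function(x) length(x@ploidy))

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nLoci(object), "loci x", nStrains(object), "strains\n")
  pl <- table(object@ploidy)
  cat("  ploidy:", paste(sprintf("%sx%s", pl, names(pl)), collapse = ", "), "\n")
  cat("  contigs:", length(unique(object@loci$contig)),
      "| biallelic loci:", sum(object@loci$biallelic), "\n")
})

#' Subset a GenotypeMatrix by loci and/or strains
#'
#' @param x A `GenotypeMatrix`.
#' @param i Locus index (logical/integer).
#' @param j Strain index (logical/integer/character).
#' @param ... ignored.
#' @param drop ignored; always returns a `GenotypeMatrix`.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nLoci(x))
  if (missing(j)) j <- seq_len(nStrains(x))
  GenotypeMatrix(x@loci[i, , drop = FALSE],
                 x@dosage[i, j, drop = FALSE],
                 x@ploidy[j])
})
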