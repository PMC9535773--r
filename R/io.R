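# IO layer: strain metadata tables, minimal VCF dialect, depth tracks,
# newick trees, FASTA region alignments. Internal coordinates are 0-based
# half-open everywhere; VCF (1-based) is converted on read/write.

#' Read a strain metadata table
#'
#' Reads a tab-separated strain table (one row per strain) with at least the
#' columns `strain_id`, `habitat`, `location`, `ploidy`. The ploidy column
#' accepts `1`, `2`, `4`, or an "unclear" marker (`unclear`, `2(?)`, `?`).
#' Habitat free text and sampling location are additionally mapped to coarse
#' categories (`habitat_category`, `continent`) used by the enrichment module.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `strain_id`, `habitat`, `habitat_category`,
#'   `location`, `continent`, `ploidy_label` (character: `"1"`, `"2"`, `"4"`,
#'   `"unclear"`, or `NA`), plus any extra columns present in the file. Row
#'   order follows the file.
#' @examples
#' tab <- readStrainTable(system.file("extdata", "hw_strains.tsv",
#'                                    package = "ClonalHybrids"))
#' table(tab$ploidy_label)
#' @export
readStrainTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  need <- c("strain_id", "habitat", "location", "ploidy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("strain table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    df$habitat_category <- character(0)
    df$continent <- character(0)
    df$ploidy_label <- character(0)
    return(df)
  }
  dup <- df$strain_id[duplicated(df$strain_id)]
  if (length(dup))
    stop("duplicate strain_id in strain table: ", paste(unique(dup), collapse = ", "))
  df$ploidy_label <- vapply(seq_len(nrow(df)), function(i) {
    parsePloidyLabel(df$ploidy[i], row = i)
  }, character(1))
  df$habitat_category <- habitatCategory(df$habitat)
  df$continent <- continentOf(df$location)
  df
}

parsePloidyLabel <- function(x, row = NA) {
  x <- trimws(x)
  if (is.na(x) || x == "" || toupper(x) == "NA") return(NA_character_)
  if (x %in% c("1", "2", "4")) return(x)
  if (grepl("\\?", x) || tolower(x) == "unclear") return("unclear")
  stop(sprintf("unparseable ploidy '%s' in strain table row %s", x, row))
}

#' Map free-text isolation habitats to coarse categories
#'
#' Keyword-based classification into `brine`, `bittern`, `seawater`, `cave`,
#' `clinical`, `tap water`, `surface`, `other`.
#'
#' @param habitat Character vector of habitat descriptions.
#' @return Character vector of categories.
#' @export
habitatCategory <- function(habitat) {
  h <- tolower(habitat)
  out <- rep("other", length(h))
  out[grepl("surface|kitchen|bathroom|dishwasher|refrigerator|sink|drain|counter|faucet|strainer|ceiling|rubber|metal|door|mesh", h)] <- "surface"
  out[grepl("tap water|well water|spring|fountain|aquarium|pond", h)] <- "tap water"
  out[grepl("cave", h)] <- "cave"
  out[grepl("seawater|marine|sea water|plankton|coral|deep sea|sea ice|glacial|soil on the sea", h)] <- "seawater"
  out[grepl("infection|tinea|kerato|mycosis|kidney|endoperitoneal|clinical", h)] <- "clinical"
  out[grepl("brine|salted|salt\\b|nacl", h)] <- "brine"
  out[grepl("bittern", h)] <- "bittern"
  out[is.na(habitat) | !nzchar(trimws(habitat))] <- NA_character_
  out
}

#' Map sampling-site locations to continents
#'
#' @param location Character vector of location descriptions.
#' @return Character vector of continents (`NA` when unknown).
#' @export
continentOf <- function(location) {
  l <- tolower(location)
  key <- list(
    Europe = c("spain", "slovenia", "greece", "italy", "france", "portugal",
               "germany", "sweden", "norway", "svalbard", "celje", "delos"),
    `South America` = c("brazil", "chile", "argentina", "atacama"),
    `North America` = c("usa", "puerto rico", "vineyard"),
    Asia = c("china", "japan", "thailand"),
    Africa = c("senegal", "namibia"))
  out <- rep(NA_character_, length(l))
  for (cont in names(key)) {
    pat <- paste(key[[cont]], collapse = "|")
    out[is.na(out) & grepl(pat, l)] <- cont
  }
  out
}

#' Read an assembly-statistics table
#'
#' TSV with columns `strain_id`, `assembly_size` (bp), `n_genes`,
#' `busco_core_mean_copy` and optionally `n_contigs`, `n50`.
#'
#' @param path Path to the TSV file.
#' @return data.frame, validated.
#' @export
readAssemblyStats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "assembly_size", "n_genes", "busco_core_mean_copy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assembly stats table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$assembly_size <= 0) || any(df$n_genes <= 0) ||
      any(df$busco_core_mean_copy < 0))
    stop("assembly stats out of range (sizes and gene counts must be positive)")
  df
}

# ---- VCF (minimal v4.2 dialect: CHROM POS ID REF ALT QUAL FILTER INFO FORMAT GT) ----

#' Read a genotype matrix from a minimal VCF
#'
#' Supports the GT-only VCF v4.2 subset this pipeline writes: unphased or
#' phased GT calls whose allele count must match the declared per-sample
#' ploidy. Multiallelic records are retained but flagged non-biallelic.
#' Missing calls (`./.`) become `NA` dosages.
#'
#' @param path Path to an uncompressed VCF file.
#' @param ploidy Named integer vector giving each sample's ploidy. Defaults to
#'   diploid for all samples.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path, ploidy = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (!length(samples)) stop("VCF has no sample columns")
  if (is.null(ploidy)) ploidy <- setNames(rep(2L, length(samples)), samples)
  if (is.null(names(ploidy))) names(ploidy) <- samples
  if (!setequal(names(ploidy), samples))
    stop("declared ploidy names do not match VCF samples")
  ploidy <- ploidy[samples]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(GenotypeMatrix(
      data.frame(contig = character(0), pos0 = integer(0), ref = character(0),
                 alt = character(0)),
      matrix(integer(0), 0, length(samples), dimnames = list(NULL, samples)),
      ploidy))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9 + length(samples)))
    stop("malformed VCF record at data line ", which(nf != 9 + length(samples))[1])
  m <- do.call(rbind, fields)
  fmt <- m[, 9]
  gtIdx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) match("GT", f), integer(1))
  if (anyNA(gtIdx)) stop("GT field absent in FORMAT at record ", which(is.na(gtIdx))[1])
  dos <- matrix(NA_integer_, nrow(m), length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    raw <- m[, 9 + j]
    gt <- vapply(seq_along(raw), function(i) {
      strsplit(raw[i], ":", fixed = TRUE)[[1]][gtIdx[i]]
    }, character(1))
    alleles <- strsplit(gt, "[/|]")
    nall <- lengths(alleles)
    bad <- nall != ploidy[j]
    if (any(bad))
      stop(sprintf("GT ploidy %d inconsistent with declared ploidy %d for sample %s at record %d",
                   nall[which(bad)[1]], ploidy[j], samples[j], which(bad)[1]))
    dos[, j] <- vapply(alleles, function(a) {
      if (any(a == ".")) NA_integer_ else sum(as.integer(a) > 0L)
    }, integer(1))
  }
  GenotypeMatrix(
    data.frame(contig = m[, 1], pos0 = as.integer(m[, 2]) - 1L,
               ref = m[, 4], alt = m[, 5], stringsAsFactors = FALSE),
    dos, ploidy)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits the GT-only VCF v4.2 dialect read by [readGenotypeVcf()]. Dosages are
#' rendered as unphased genotypes with the alternate alleles listed first
#' (e.g. dosage 1 of a diploid becomes `0/1`); for multiallelic loci all
#' non-reference copies are written as allele 1, which round-trips the dosage
#' (the pipeline consumes dosages, not allele identities).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  pl <- strainPloidy(gm)
  lo <- loci(gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ClonalHybrids",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", names(pl)), collapse = "\t")),
             con)
  if (nLoci(gm) == 0) return(invisible(path))
  gtCol <- function(d, p) {
    vapply(d, function(k) {
      if (is.na(k)) paste(rep(".", p), collapse = "/")
      else paste(c(rep("1", k), rep("0", p - k)), collapse = "/")
    }, character(1))
  }
  gts <- mapply(gtCol, asplit(dosage(gm), 2), pl)
  recs <- paste(lo$contig, lo$pos0 + 1L, ".", lo$ref, lo$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  writeLines(paste(recs, apply(gts, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

# ---- depth tracks (BedGraph-like TSV: contig, start, end, depth) ----

#' Read a raw depth track
#'
#' BedGraph-like TSV with header `contig start end depth`; intervals are
#' 0-based half-open and must tile each contig without overlap.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `contig`, `start`, `end`, `depth`.
#' @export
readDepthTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "depth")
  if (!all(need %in% names(df)))
    stop("depth track must have columns ", paste(need, collapse = ", "))
  if (any(df$depth < 0)) stop("negative depth values")
  for (ct in unique(df$contig)) {
    d <- df[df$contig == ct, ]
    d <- d[order(d$start), ]
    if (any(d$end <= d$start) || any(head(d$end, -1) > tail(d$start, -1)))
      stop("depth windows overlap or are empty on contig ", ct)
  }
  df
}

#' @rdname readDepthTsv
#' @param depth data.frame as returned by [readDepthTsv()] or [simulateDepth()].
#' @export
writeDepthTsv <- function(depth, path) {
  write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- newick ----

#' Read and write newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Leaf labels follow the subgenome convention: a strain id, optionally with a
#' letter suffix (`"12a"`) for one subgenome of a strain with ploidy > 1.
#' `readNewick` reports the character offset of the first unbalanced
#' parenthesis on malformed input.
#'
#' @param text Newick string (or path via `file`).
#' @param file Optional path to read from / write to.
#' @return `readNewick`: an [ape::phylo] tree. `writeNewick`: the newick
#'   string (invisibly the path when `file` is given).
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop("newick parse error: unbalanced ')' at character ", which(depth < 0)[1])
  if (length(depth) && tail(depth, 1) != 0)
    stop("newick parse error: ", tail(depth, 1), " unclosed '(' at character ",
         length(chars))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: could not parse tree")
  tr
}

#' @rdname readNewick
#' @param tree An [ape::phylo] tree with >= 2 leaves.
#' @export
writeNewick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 leaves")
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

# ---- FASTA region alignments ----

#' Read a directory of per-region FASTA alignments
#'
#' Each `*.fasta`/`*.fa` file is one aligned region; sequence names follow
#' the subgenome convention (`strain` or `strain + letter`).
#'
#' @param dir Directory containing FASTA files.
#' @return Named list of [Biostrings::DNAStringSet] alignments (names are the
#'   file basenames without extension).
#' @export
readRegionAlignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", dir)
  out <- lapply(files, Biostrings::readDNAStringSet)
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}

#' @rdname readRegionAlignments
#' @param alignments Named list of `DNAStringSet` alignments.
#' @export
writeRegionAlignments <- function(alignments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(alignments))
    Biostrings::writeXStringSet(alignments[[nm]],
                                file.path(dir, paste0(nm, ".fasta")))
  invisible(dir)
}
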