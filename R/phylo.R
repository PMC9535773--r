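# Per-region distance trees with multilabeled leaves (one leaf per subgenome
# of a hybrid), cross-region concordance — the clonality criterion — and
# grouping of diploids into hybridization events by subgenome lineage
# clustering.

# Infer strain id and subgenome letter from leaf labels: labels of
# multi-copy strains end in a letter (a-d) appended to the strain id.
parseLeafLabels <- function(labels) {
  stem <- sub("([a-d])$", "", labels)
  letter <- ifelse(stem == labels, "", sub("^.*?([a-d])$", "\\1", labels))
  multi <- stem %in% stem[duplicated(stem)] | letter != ""
  data.frame(label = labels, strain = ifelse(multi, stem, labels),
             subgenome = ifelse(multi, letter, "a"),
             stringsAsFactors = FALSE)
}

#' Filter and select region alignments
#'
#' Applies the ploidy-match filter (each strain must contribute exactly
#' `ploidy` sequences to a region, else the region is rejected), the
#' per-sequence gap-fraction filter, then keeps the `n` longest surviving
#' regions (ties broken by region id).
#'
#' @param alignments Named list of `DNAStringSet` alignments.
#' @param ploidy Named integer vector of per-strain ploidy.
#' @param n Number of regions to keep (default 50); a warning is issued and
#'   all survivors returned when fewer survive.
#' @param maxGapFraction Maximum allowed gap fraction in any sequence
#'   (default 0.15; 0.25 is the lenient variant used for more fragmented
#'   assemblies).
#' @return Named list of surviving alignments, longest first.
#' @export
selectRegions <- function(alignments, ploidy, n = 50L, maxGapFraction = 0.15) {
  ok <- vapply(alignments, function(aln) {
    info <- parseLeafLabels(names(aln))
    counts <- table(info$strain)
    if (!all(names(counts) %in% names(ploidy))) return(FALSE)
    if (length(counts) != length(ploidy)) return(FALSE)
    if (!all(counts[names(ploidy)] == ploidy)) return(FALSE)
    gapFrac <- Biostrings::letterFrequency(aln, "-") / Biostrings::width(aln)
    all(gapFrac <= maxGapFraction)
  }, logical(1))
  surv <- alignments[ok]
  if (!length(surv)) stop("no region passed the ploidy/gap filters")
  len <- vapply(surv, function(a) Biostrings::width(a)[1], integer(1))
  ord <- order(-len, names(surv))
  surv <- surv[ord]
  if (length(surv) < n)
    warning("only ", length(surv), " regions survive filtering; using all")
  surv[seq_len(min(n, length(surv)))]
}

alignmentPDistance <- function(aln) {
  bin <- ape::as.DNAbin(aln)
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  d[order(rownames(d)), order(colnames(d))]
}

#' Neighbor-joining tree for one region alignment
#'
#' Pairwise p-distance (fraction of differing non-gap columns) followed by
#' neighbor joining; negative branch lengths are clamped to zero. NJ is
#' consistent on additive distances, so on infinite-sites data with adequate
#' region length it recovers the shared clonal genealogy; it stands in for
#' full ML inference because the downstream readouts (concordance, event
#' grouping) depend only on topology and approximate branch lengths.
#'
#' @param aln A `DNAStringSet` alignment with >= 3 sequences.
#' @return An [ape::phylo] tree whose tips are subgenome labels.
#' @export
regionTree <- function(aln) {
  if (length(aln) < 3) stop("alignment must have >= 3 sequences")
  d <- alignmentPDistance(aln)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

rootAtReference <- function(trees) {
  ref <- sort(trees[[1]]$tip.label)[1]
  lapply(trees, function(t) ape::root(t, outgroup = ref, resolve.root = TRUE))
}

#' Clade support across region trees
#'
#' For every clade observed in at least one tree (trees rooted at a common
#' reference leaf so clades correspond to splits), the support is the
#' fraction of trees containing it. Also returns the strict majority-rule
#' consensus (clades with support > 0.5).
#'
#' @param trees List of [ape::phylo] trees over one shared leaf set.
#' @return list with `support` (data.frame `clade, count, support`; `clade`
#'   is a comma-joined sorted leaf subset) and `consensus` (phylo).
#' @export
cladeSupport <- function(trees) {
  if (length(trees) < 1) stop("need >= 1 tree")
  sets <- lapply(trees, function(t) sort(t$tip.label))
  for (s in sets[-1]) if (!identical(s, sets[[1]]))
    stop("trees differ in leaf sets; symmetric difference: ",
         paste(union(setdiff(s, sets[[1]]), setdiff(sets[[1]], s)),
               collapse = ", "))
  rooted <- rootAtReference(trees)
  class(rooted) <- "multiPhylo"
  pp <- ape::prop.part(rooted)
  labs <- attr(pp, "labels")
  support <- data.frame(
    clade = vapply(pp, function(i) paste(sort(labs[i]), collapse = ","),
                   character(1)),
    count = attr(pp, "number"),
    support = attr(pp, "number") / length(trees),
    stringsAsFactors = FALSE)
  support <- support[order(-support$support, support$clade), ]
  rownames(support) <- NULL
  nt <- length(trees)
  cons <- ape::consensus(rooted, p = 0.5 + 1 / (2 * nt))
  list(support = support, consensus = cons)
}

#' Cross-region concordance score
#'
#' Mean over tree pairs of one minus the normalized Robinson-Foulds
#' distance: 1 when all regions share one topology (the "strong phylogenetic
#' signal" criterion for clonality), 0 when every resolvable split
#' conflicts.
#'
#' @param trees List of >= 2 [ape::phylo] trees over one shared leaf set.
#' @return Numeric scalar in `[0, 1]`.
#' @export
concordanceScore <- function(trees) {
  if (length(trees) < 2) stop("need >= 2 trees")
  class(trees) <- "multiPhylo"
  rf <- phangorn::RF.dist(trees, normalize = TRUE)
  mean(1 - as.vector(rf))
}

#' Average subgenome distance matrix across regions
#'
#' Mean p-distance between subgenome leaves over all regions (regions must
#' share the leaf set, as guaranteed by [selectRegions()]).
#'
#' @param alignments Named list of `DNAStringSet` alignments.
#' @return Symmetric numeric matrix over subgenome labels.
#' @export
averageSubgenomeDistance <- function(alignments) {
  mats <- lapply(alignments, alignmentPDistance)
  Reduce(`+`, mats) / length(mats)
}

#' Assign subgenomes to haploid lineage clusters
#'
#' Single-linkage clustering of the average subgenome distance matrix at
#' threshold `tauLineage` (default: half the median distance between haploid
#' strains) groups subgenomes into lineage clusters. A cluster containing at
#' least one haploid strain is named after it; clusters made only of hybrid
#' subgenomes get synthetic lineage ids (`anon1`, ...) — the
#' extinct-or-unsampled-parent case. A subgenome whose nearest distances to
#' two clusters differ by less than `ambigTol` is flagged ambiguous.
#'
#' @param D Matrix from [averageSubgenomeDistance()].
#' @param tauLineage Clustering threshold; `NULL` for the default.
#' @param ambigTol Ambiguity tolerance (default `0.1 * tauLineage`).
#' @return data.frame `label, strain, subgenome, lineage, ambiguous` plus
#'   attributes `tauLineage`.
#' @export
assignSubgenomes <- function(D, tauLineage = NULL, ambigTol = NULL) {
  info <- parseLeafLabels(rownames(D))
  ploidy <- table(info$strain)
  haploids <- names(ploidy)[ploidy == 1]
  if (is.null(tauLineage)) {
    if (length(haploids) < 2)
      stop("tauLineage must be given when fewer than 2 haploid strains exist")
    hd <- D[haploids, haploids]
    tauLineage <- 0.5 * median(hd[upper.tri(hd)])
  }
  if (is.null(ambigTol)) ambigTol <- 0.1 * tauLineage
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  cl <- stats::cutree(hc, h = tauLineage)
  lineageName <- vapply(sort(unique(cl)), function(k) {
    members <- info$strain[cl == k]
    hap <- intersect(haploids, members)
    if (length(hap)) sort(hap)[1] else NA_character_
  }, character(1))
  anon <- which(is.na(lineageName))
  lineageName[anon] <- paste0("anon", seq_along(anon))
  info$lineage <- lineageName[cl]
  # ambiguity: gap between nearest own-cluster vs nearest other-cluster leaf
  info$ambiguous <- vapply(seq_len(nrow(info)), function(i) {
    own <- which(cl == cl[i]); own <- setdiff(own, i)
    other <- which(cl != cl[i])
    if (!length(own) || !length(other)) return(FALSE)
    abs(min(D[i, other]) - min(D[i, own])) < ambigTol
  }, logical(1))
  attr(info, "tauLineage") <- tauLineage
  info
}

#' Group diploids into hybridization events
#'
#' Diploids sharing one unordered parental-lineage pair are linked when both
#' corresponding subgenome pairs are closer than `tauEvent`; connected
#' components of this graph are the hybridization-event groups. Strains with
#' ambiguous or incomplete assignments are reported under `unplaced`, never
#' silently dropped; tetraploids are reported separately with their four
#' lineage assignments.
#'
#' @param assignment data.frame from [assignSubgenomes()].
#' @param D Matrix from [averageSubgenomeDistance()].
#' @param tauEvent Linking threshold; default is 5 times the median
#'   nearest-neighbour distance among diploid subgenomes within a lineage
#'   cluster (an estimate of the post-hybridization divergence scale).
#' @return list of class `HybridEventGroups`: `groups` (data.frame
#'   `event_id, parents, members, n_members`), `assignment` of members,
#'   `unplaced` (character), `tetraploids` (data.frame `strain, lineages`),
#'   `tauEvent`.
#' @export
inferHybridEvents <- function(assignment, D, tauEvent = NULL) {
  info <- assignment
  ploidy <- table(info$strain)
  dipStrains <- names(ploidy)[ploidy == 2]
  tetStrains <- names(ploidy)[ploidy == 4]
  unplaced <- unique(info$strain[info$ambiguous])
  dip <- setdiff(dipStrains, unplaced)
  dipInfo <- info[info$strain %in% dip, ]
  if (is.null(tauEvent)) {
    nn <- vapply(which(info$strain %in% dipStrains), function(i) {
      same <- which(info$lineage == info$lineage[i] &
                    info$strain != info$strain[i])
      if (!length(same)) return(NA_real_)
      min(D[i, same])
    }, numeric(1))
    tauEvent <- 5 * median(nn, na.rm = TRUE)
    if (is.na(tauEvent)) tauEvent <- 0
  }
  pairKey <- vapply(dip, function(s) {
    paste(sort(dipInfo$lineage[dipInfo$strain == s]), collapse = "|")
  }, character(1))
  edges <- matrix(character(0), ncol = 2)
  if (length(dip) >= 2) {
    cmb <- combn(dip, 2)
    linked <- vapply(seq_len(ncol(cmb)), function(k) {
      s1 <- cmb[1, k]; s2 <- cmb[2, k]
      if (pairKey[[s1]] != pairKey[[s2]]) return(FALSE)
      i1 <- dipInfo[dipInfo$strain == s1, ]
      i2 <- dipInfo[dipInfo$strain == s2, ]
      # match subgenomes by assigned lineage (the letter order within a
      # strain is arbitrary); fall back to positional matching if both
      # subgenomes landed in one cluster
      all(vapply(seq_len(nrow(i1)), function(r) {
        j <- if (anyDuplicated(i1$lineage)) r
             else which(i2$lineage == i1$lineage[r])[1]
        D[i1$label[r], i2$label[j]] <= tauEvent
      }, logical(1)))
    }, logical(1))
    edges <- t(cmb[, linked, drop = FALSE])
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = dip, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  groups <- do.call(rbind, lapply(sort(unique(comp)), function(k) {
    members <- sort(names(comp)[comp == k])
    data.frame(parents = pairKey[[members[1]]],
               members = paste(members, collapse = ","),
               n_members = length(members), stringsAsFactors = FALSE)
  }))
  if (is.null(groups))
    groups <- data.frame(parents = character(0), members = character(0),
                         n_members = integer(0))
  groups <- groups[order(-groups$n_members, groups$parents), , drop = FALSE]
  groups <- cbind(event_id = sprintf("G%02d", seq_len(nrow(groups))), groups)
  rownames(groups) <- NULL
  tet <- do.call(rbind, lapply(tetStrains, function(s) {
    data.frame(strain = s,
               lineages = paste(sort(info$lineage[info$strain == s]),
                                collapse = ","),
               stringsAsFactors = FALSE)
  })) %||% data.frame(strain = character(0), lineages = character(0))
  structure(list(groups = groups, assignment = dipInfo,
                 unplaced = intersect(unplaced, dipStrains),
                 tetraploids = tet, tauEvent = tauEvent),
            class = "HybridEventGroups")
}

#' @export
print.HybridEventGroups <- function(x, ...) {
  cat("HybridEventGroups:", nrow(x$groups), "event group(s),",
      sum(x$groups$n_members), "diploid(s) placed,",
      length(x$unplaced), "unplaced\n")
  if (nrow(x$groups)) print(x$groups, row.names = FALSE)
  invisible(x)
}

#' End-to-end hybridization-event inference from region alignments
#'
#' Convenience wrapper: filter regions, average the subgenome distances,
#' assign lineage clusters, and group diploids into events.
#'
#' @param alignments Named list of `DNAStringSet` region alignments.
#' @param ploidy Named per-strain ploidy vector.
#' @param n Number of regions to use.
#' @param maxGapFraction Gap filter threshold.
#' @param tauLineage,tauEvent Optional thresholds (see
#'   [assignSubgenomes()], [inferHybridEvents()]).
#' @return A `HybridEventGroups` list (see [inferHybridEvents()]).
#' @export
hybridEventsFromAlignments <- function(alignments, ploidy, n = 50L,
                                       maxGapFraction = 0.15,
                                       tauLineage = NULL, tauEvent = NULL) {
  regs <- selectRegions(alignments, ploidy, n = n,
                        maxGapFraction = maxGapFraction)
  D <- averageSubgenomeDistance(regs)
  asg <- assignSubgenomes(D, tauLineage = tauLineage)
  inferHybridEvents(asg, D, tauEvent = tauEvent)
}
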