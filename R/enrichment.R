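# Habitat / geography enrichment of hybrid and haploid strain groups:
# Fisher's exact test with a Monte-Carlo (simulated) p-value on the
# group x category contingency table.

#' Build a group-by-category contingency table
#'
#' Cross-tabulates strains by their group (e.g. hybridization-event group)
#' and a metadata field (e.g. `habitat_category` or `continent`). Strains
#' lacking a group or a field value are excluded and counted in the
#' `excluded` attribute, never silently dropped.
#'
#' @param meta data.frame from [readStrainTable()] (needs `strain_id` and
#'   the requested field).
#' @param groups Named character vector mapping `strain_id` to group.
#' @param field Metadata column to tabulate against.
#' @return Integer matrix (groups x categories) with attribute `excluded`.
#' @export
buildContingency <- function(meta, groups, field = "habitat_category") {
  if (!field %in% names(meta)) stop("no column '", field, "' in metadata")
  g <- groups[meta$strain_id]
  v <- meta[[field]]
  ok <- !is.na(g) & !is.na(v) & nzchar(v)
  if (!any(ok)) stop("contingency table is empty after exclusions")
  tab <- table(group = g[ok], category = v[ok])
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  attr(out, "excluded") <- sum(!ok)
  out
}

logTableProb <- function(tab) {
  # multivariate hypergeometric probability of a table with fixed margins
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Full enumeration: the p-value is the sum of hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' the observed table's (with a small relative tolerance for float ties).
#'
#' @param tab 2x2 integer matrix.
#' @return Exact two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2))  # 2 / choose(20, 10)
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Monte-Carlo Fisher test for an r x c table
#'
#' Simulated p-value: `nSim` random tables with the observed margins are
#' drawn (Patefield algorithm via [stats::r2dtable()]) and
#' `p = (1 + #\{P(sim) <= P(obs)\}) / (nSim + 1)` — the add-one estimator
#' standard for simulated exact tests.
#'
#' @param tab Integer matrix of counts (no all-zero row or column).
#' @param nSim Number of simulated tables (default 10,000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return list `p.value`, `nSim`, `seed`.
#' @export
fisherExactMC <- function(tab, nSim = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margins: remove all-zero rows/columns first")
  lpObs <- logTableProb(tab)
  withSeed(seed, {
    sims <- r2dtable(nSim, rs, cs)
    lp <- vapply(sims, logTableProb, numeric(1))
    p <- (1 + sum(lp <= lpObs + 1e-7)) / (nSim + 1)
    list(p.value = p, nSim = nSim, seed = seed)
  })
}

#' Group-enrichment test for a metadata field
#'
#' Builds the contingency table and runs the Monte-Carlo Fisher test, the
#' procedure used to ask whether hybridization-event groups are skewed
#' toward particular habitats or continents.
#'
#' @inheritParams buildContingency
#' @inheritParams fisherExactMC
#' @return list `table`, `p.value`, `excluded`, `nSim`, `seed`.
#' @export
testGroupEnrichment <- function(meta, groups, field = "habitat_category",
                                nSim = 10000L, seed = 1L) {
  tab <- buildContingency(meta, groups, field)
  keep <- rowSums(tab) > 0
  tab2 <- tab[keep, colSums(tab) > 0, drop = FALSE]
  res <- fisherExactMC(tab2, nSim = nSim, seed = seed)
  list(table = tab, p.value = res$p.value,
       excluded = attr(tab, "excluded"), nSim = nSim, seed = seed)
}
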