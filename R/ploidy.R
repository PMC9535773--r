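# Ploidy classification from assembly statistics: genome size, predicted
# gene count, and mean copy number of core BUSCOs, with a joint-criteria
# rule — any value falling between the haploid and diploid bands, or a mixed
# pattern, yields "unclear".

#' Ploidy classification thresholds
#'
#' Returns the classification bands. The haploid band (genome size < 31 Mbp,
#' genes < 13,000, core-BUSCO mean copy < 1.1) and diploid band (size >
#' 46 Mbp, genes > 18,000, copy > 1.5) follow the published criteria for the
#' black-yeast genomes. The tetraploid band is not published (only one
#' tetraploid was ever observed); its defaults sit midway between the diploid
#' and the observed tetraploid values and are configurable.
#'
#' @param haploid_max_size,haploid_max_genes,haploid_max_copy Upper limits of
#'   the haploid band.
#' @param diploid_min_size,diploid_min_genes,diploid_min_copy Lower limits of
#'   the diploid band.
#' @param tetraploid_min_size,tetraploid_min_genes Lower limits of the
#'   tetraploid band.
#' @return Named list of thresholds.
#' @export
ploidyThresholds <- function(haploid_max_size = 31e6,
                             haploid_max_genes = 13000,
                             haploid_max_copy = 1.1,
                             diploid_min_size = 46e6,
                             diploid_min_genes = 18000,
                             diploid_min_copy = 1.5,
                             tetraploid_min_size = 80e6,
                             tetraploid_min_genes = 36000) {
  th <- list(haploid_max_size = haploid_max_size,
             haploid_max_genes = haploid_max_genes,
             haploid_max_copy = haploid_max_copy,
             diploid_min_size = diploid_min_size,
             diploid_min_genes = diploid_min_genes,
             diploid_min_copy = diploid_min_copy,
             tetraploid_min_size = tetraploid_min_size,
             tetraploid_min_genes = tetraploid_min_genes)
  if (!(haploid_max_size < diploid_min_size &&
        diploid_min_size < tetraploid_min_size &&
        haploid_max_genes < diploid_min_genes &&
        diploid_min_genes < tetraploid_min_genes &&
        haploid_max_copy < diploid_min_copy))
    stop("ploidy thresholds must satisfy haploid < diploid < tetraploid bands")
  th
}

#' Mean copy number of core BUSCOs per strain
#'
#' "Core" BUSCOs are those present (copy >= 1) in every strain of the set;
#' the statistic per strain is the arithmetic mean copy number over that
#' core set. Mean copy near 1 indicates a haploid assembly, near 2 a diploid
#' assembly with both haplotypes assembled.
#'
#' @param buscoTable data.frame `busco_id, strain_id, copies` (absent
#'   combinations count as copy 0).
#' @param strains Strain set defining the core (default: all strains in the
#'   table).
#' @return Named numeric vector of per-strain mean core copy numbers.
#' @export
coreBuscoMeanCopy <- function(buscoTable, strains = NULL) {
  need <- c("busco_id", "strain_id", "copies")
  if (!all(need %in% names(buscoTable)))
    stop("busco table must have columns ", paste(need, collapse = ", "))
  if (is.null(strains)) strains <- unique(buscoTable$strain_id)
  tab <- buscoTable[buscoTable$strain_id %in% strains, ]
  wide <- matrix(0, nrow = length(unique(tab$busco_id)), ncol = length(strains),
                 dimnames = list(unique(tab$busco_id), strains))
  wide[cbind(match(tab$busco_id, rownames(wide)),
             match(tab$strain_id, strains))] <- tab$copies
  core <- rowSums(wide >= 1) == length(strains)
  if (!any(core))
    stop("empty core BUSCO set: no BUSCO is present in every strain; ",
         "the strain set may be too heterogeneous")
  colMeans(wide[core, , drop = FALSE])
}

#' Classify strain ploidy from assembly statistics
#'
#' Applies the joint-criteria rule: the tetraploid band is checked first,
#' then the diploid band (all of size, gene count and BUSCO copy must agree),
#' then the haploid band. Any value between bands, or a mixed pattern,
#' yields `"unclear"`. Per-criterion verdicts are recorded.
#'
#' @param stats data.frame with columns `strain_id`, `assembly_size`,
#'   `n_genes`, `busco_core_mean_copy`.
#' @param thresholds As returned by [ploidyThresholds()].
#' @return data.frame `strain_id, call, size_verdict, genes_verdict,
#'   copy_verdict`; `call` is one of `"1"`, `"2"`, `"4"`, `"unclear"`.
#' @examples
#' classifyPloidy(data.frame(strain_id = "s1", assembly_size = 26.5e6,
#'                           n_genes = 9519, busco_core_mean_copy = 1.02))
#' @export
classifyPloidy <- function(stats, thresholds = ploidyThresholds()) {
  th <- thresholds
  band <- function(x, hiMax, loMin) {
    ifelse(x < hiMax, "haploid", ifelse(x > loMin, "diploid", "between"))
  }
  sizeV <- band(stats$assembly_size, th$haploid_max_size, th$diploid_min_size)
  genesV <- band(stats$n_genes, th$haploid_max_genes, th$diploid_min_genes)
  copyV <- band(stats$busco_core_mean_copy, th$haploid_max_copy,
                th$diploid_min_copy)
  sizeV[stats$assembly_size >= th$tetraploid_min_size] <- "tetraploid"
  genesV[stats$n_genes >= th$tetraploid_min_genes] <- "tetraploid"
  call <- rep("unclear", nrow(stats))
  call[sizeV == "tetraploid" & genesV == "tetraploid"] <- "4"
  isDip <- sizeV == "diploid" & genesV == "diploid" & copyV == "diploid"
  call[call == "unclear" & isDip] <- "2"
  isHap <- sizeV == "haploid" & genesV == "haploid" & copyV == "haploid"
  call[call == "unclear" & isHap] <- "1"
  data.frame(strain_id = stats$strain_id, call = call,
             size_verdict = sizeV, genes_verdict = genesV,
             copy_verdict = copyV, stringsAsFactors = FALSE)
}
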