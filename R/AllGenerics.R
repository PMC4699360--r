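#' Cohort labels of the samples
#' @param x a [CohortCountSet-class].
#' @return character vector, one label per sample.
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' Library sizes (column sums) of a count container
#' @param x a [CohortCountSet-class].
#' @return named numeric vector of per-sample totals.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' Gene ids of a signed gene list
#' @param x a [SignedGeneList-class].
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Direction signs of a signed gene list
#' @param x a [SignedGeneList-class].
#' @return named integer vector of +1/-1, one per gene.
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' Contrast name of a signed gene list
#' @param x a [SignedGeneList-class].
#' @return single character.
#' @export
setGeneric("contrastName", function(x) standardGeneric("contrastName"))

#' LAG core of a longevity network
#' @param x a [LongevityNetwork-class].
#' @return character vector of core gene ids.
#' @export
setGeneric("lagCore", function(x) standardGeneric("lagCore"))

#' First-order partners of the LAG core
#' @param x a [LongevityNetwork-class].
#' @return character vector of partner gene ids.
#' @export
setGeneric("partnerGenes", function(x) standardGeneric("partnerGenes"))

#' All nodes of the retained (largest connected) component
#' @param x a [LongevityNetwork-class].
#' @return character vector of node ids.
#' @export
setGeneric("componentNodes", function(x) standardGeneric("componentNodes"))

#' Planted block gene sets
#' @param x a [PlantedTruth-class].
#' @return named list of character vectors.
#' @export
setGeneric("plantedBlocks", function(x) standardGeneric("plantedBlocks"))
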