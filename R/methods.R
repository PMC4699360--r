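#' @describeIn CohortCountSet cohort label per sample
#' @param x a `CohortCountSet`.
#' @export
setMethod("cohorts", "CohortCountSet", function(x)
  as.character(SummarizedExperiment::colData(x)$cohort))

#' @describeIn CohortCountSet per-sample library sizes (column sums)
#' @export
setMethod("librarySizes", "CohortCountSet", function(x)
  colSums(SummarizedExperiment::assay(x, "counts")))

setMethod("show", "CohortCountSet", function(object) {
  cat("CohortCountSet:", nrow(object), "genes x", ncol(object), "samples\n")
  tab <- table(cohorts(object))
  cat("cohorts:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  invisible(callNextMethod())
})

#' @describeIn SignedGeneList gene ids
#' @param x a `SignedGeneList`.
#' @export
setMethod("geneIds", "SignedGeneList", function(x) x@genes)

#' @describeIn SignedGeneList direction signs (+1 / -1), named by gene
#' @export
setMethod("directions", "SignedGeneList", function(x)
  setNames(as.integer(sign(x@log2FC)), x@genes))

#' @describeIn SignedGeneList contrast name
#' @export
setMethod("contrastName", "SignedGeneList", function(x) x@contrast)

#' @describeIn SignedGeneList number of genes in the list
#' @export
setMethod("length", "SignedGeneList", function(x) length(x@genes))

setMethod("show", "SignedGeneList", function(object) {
  cat("SignedGeneList '", object@contrast, "': ", length(object),
      " genes (", sum(object@log2FC > 0), " up, ",
      sum(object@log2FC < 0), " down)\n", sep = "")
  if (length(object))
    cat("  head:", paste(head(object@genes, 5), collapse = ", "), "\n")
})

#' Convert a SignedGeneList to a data.frame
#'
#' @param x a [SignedGeneList-class].
#' @param ... ignored.
#' @return data.frame with columns `gene`, `log2FC`, `direction`, `fdr`
#'   plus any `info` columns.
#' @method as.data.frame SignedGeneList
#' @export
as.data.frame.SignedGeneList <- function(x, ...) {
  d <- data.frame(gene = x@genes, log2FC = x@log2FC,
                  direction = as.integer(sign(x@log2FC)), fdr = x@fdr,
                  stringsAsFactors = FALSE)
  if (!is.null(x@info)) d <- cbind(d, x@info)
  d
}
setMethod("as.data.frame", "SignedGeneList",
          function(x, ...) as.data.frame.SignedGeneList(x, ...))

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign with", nrow(object@design), "cohorts",
      sprintf("(reference: %s)\n", referenceCohort(object)))
  print(object@design, row.names = FALSE)
})

#' Reference cohort label of a design
#' @param design a [CohortDesign-class].
#' @return single character.
#' @export
referenceCohort <- function(design)
  design@design$cohort[design@design$reference]

#' Cohort labels of a design
#' @param design a [CohortDesign-class].
#' @return character vector.
#' @export
cohortLabels <- function(design) design@design$cohort

#' Extended-longevity cohorts of a design (excluding the reference)
#' @param design a [CohortDesign-class].
#' @return character vector.
#' @export
extendedCohorts <- function(design) {
  d <- design@design
  d$cohort[d$longevityClass == "extended" & !d$reference]
}

#' Baseline-longevity, LA-supplemented cohorts of a design
#'
#' The cohorts that received lipoic acid yet showed no longevity
#' extension; these define the same-trend exclusion of the longevity-gene
#' derivation.
#' @param design a [CohortDesign-class].
#' @return character vector.
#' @export
baselineLaCohorts <- function(design) {
  d <- design@design
  d$cohort[d$longevityClass == "baseline" & d$laSupplemented & !d$reference]
}

#' @describeIn PlantedTruth named list of planted block gene sets
#' @param x a `PlantedTruth`.
#' @export
setMethod("plantedBlocks", "PlantedTruth", function(x) x@blocks)

setMethod("show", "PlantedTruth", function(object) {
  sizes <- vapply(object@blocks, length, 0L)
  cat("PlantedTruth:", length(object@geneIds), "genes;",
      sum(sizes), "planted in", length(sizes), "blocks\n")
  if (length(sizes))
    cat(paste0("  ", names(sizes), ": ", sizes, collapse = "\n"), "\n")
})

#' @describeIn LongevityNetwork LAG core genes
#' @param x a `LongevityNetwork`.
#' @export
setMethod("lagCore", "LongevityNetwork", function(x) x@lagCore)

#' @describeIn LongevityNetwork first-order partner genes
#' @export
setMethod("partnerGenes", "LongevityNetwork", function(x) x@partners)

#' @describeIn LongevityNetwork nodes of the retained component
#' @export
setMethod("componentNodes", "LongevityNetwork", function(x)
  igraph::V(x@graph)$name)

setMethod("show", "LongevityNetwork", function(object) {
  cat("LongevityNetwork (", object@species, "): ",
      length(object@lagCore), " LAG core, ", length(object@partners),
      " partners, ", igraph::vcount(object@graph), " component nodes\n",
      sep = "")
  if (length(object@droppedLags))
    cat("  LAGs outside the largest component:",
        length(object@droppedLags), "\n")
})

setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap ", object@speciesFrom, " -> ", object@speciesTo, ": ",
      nrow(object@pairs), " pairs (",
      length(unique(object@pairs$source)), " source genes)\n", sep = "")
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult: k = %d of query %d vs target %d in universe %d; one-tailed p = %.3g\n",
    object@k, object@q, object@t, object@u, object@p))
})

#' Convert an OverlapResult to a one-row data.frame
#' @param x an [OverlapResult-class].
#' @param ... ignored.
#' @return data.frame with columns `k`, `q`, `t`, `u`, `p`.
#' @method as.data.frame OverlapResult
#' @export
as.data.frame.OverlapResult <- function(x, ...)
  data.frame(k = x@k, q = x@q, t = x@t, u = x@u, p = x@p)
setMethod("as.data.frame", "OverlapResult",
          function(x, ...) as.data.frame.OverlapResult(x, ...))

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nGenes, "genes,",
      nrow(object@design@design), "cohorts x",
      object@samplesPerCohort, "libraries; seed", object@seed, "\n")
  sizes <- vapply(object@blocks, function(b) b$size, 0)
  if (length(sizes))
    cat("  blocks:", paste0(names(sizes), "(", sizes, ")", collapse = " "),
        "\n")
})
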