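#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats dnbinom dpois optimize quantile rnbinom rpois runif
#'   rbinom rlnorm rgamma setNames
#' @importFrom utils head read.delim write.table
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Cohort-labelled count container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one
#' `"counts"` assay of non-negative integer counts (genes x samples) and a
#' mandatory `cohort` column in `colData` assigning every sample (library)
#' to a diet cohort.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [CohortCountSet()] for the constructor, [cohorts()],
#'   [librarySizes()].
#' @export
setClass("CohortCountSet", contains = "SummarizedExperiment")

.validCohortCountSet <- function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cnt)))
      msg <- c(msg, "counts must be finite")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (max(abs(cnt - round(cnt))) > 1e-8)
        msg <- c(msg, "counts must be integers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  if (!"cohort" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'cohort' column")
  else if (anyNA(SummarizedExperiment::colData(object)$cohort))
    msg <- c(msg, "every sample needs a cohort label")
  if (is.null(msg)) TRUE else msg
}
setValidity("CohortCountSet", .validCohortCountSet)

#' Construct a CohortCountSet
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param cohort character vector (length `ncol(counts)`) of cohort labels.
#' @param age optional numeric vector of ages (months) per sample.
#' @return A [CohortCountSet-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cs <- CohortCountSet(m, cohort = rep(c("AL", "CR"), each = 2))
#' cohorts(cs)
#' @export
CohortCountSet <- function(counts, cohort, age = NULL) {
  counts <- as.matrix(counts)
  cd <- S4Vectors::DataFrame(cohort = as.character(cohort),
                             row.names = colnames(counts))
  if (!is.null(age)) cd$age <- age
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("CohortCountSet", se)
}

#' Signed differential-expression gene list
#'
#' The DE calls of one named contrast: gene ids with their log2 fold
#' changes and FDR values. The direction of each gene is the sign of its
#' log2 fold change; zero fold changes are not representable by design.
#'
#' @slot contrast single character, the contrast name (e.g. `"CR_vs_AL"`).
#' @slot genes character vector of unique gene ids.
#' @slot log2FC numeric vector of non-zero log2 fold changes.
#' @slot fdr numeric vector of BH-adjusted p-values in `[0, 1]`.
#' @slot info optional `data.frame` of per-gene annotations (same row
#'   count as genes), e.g. source-list tags from the dietary-memory
#'   derivation.
#' @seealso [SignedGeneList()], [callDE()], [signedIntersect()].
#' @export
setClass("SignedGeneList",
         representation(contrast = "character", genes = "character",
                        log2FC = "numeric", fdr = "numeric",
                        info = "data.frameOrNULL"),
         prototype(contrast = NA_character_, genes = character(),
                   log2FC = numeric(), fdr = numeric(), info = NULL))

.validSignedGeneList <- function(object) {
  msg <- NULL
  n <- length(object@genes)
  if (length(object@contrast) != 1L)
    msg <- c(msg, "contrast must be a single name")
  if (length(object@log2FC) != n || length(object@fdr) != n)
    msg <- c(msg, "genes, log2FC and fdr must have equal length")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene ids must be unique")
  if (n && (any(!is.finite(object@log2FC)) || any(object@log2FC == 0)))
    msg <- c(msg, "log2FC must be finite and non-zero (direction = sign)")
  if (n && (anyNA(object@fdr) || any(object@fdr < 0 | object@fdr > 1)))
    msg <- c(msg, "fdr must lie in [0, 1]")
  if (!is.null(object@info) && nrow(object@info) != n)
    msg <- c(msg, "info must have one row per gene")
  if (is.null(msg)) TRUE else msg
}
setValidity("SignedGeneList", .validSignedGeneList)

#' Construct a SignedGeneList
#'
#' @param contrast contrast name.
#' @param genes character vector of gene ids.
#' @param log2FC non-zero log2 fold changes, one per gene.
#' @param fdr BH-adjusted p-values, one per gene (default 0 for lists
#'   derived by set algebra rather than testing).
#' @param info optional per-gene `data.frame`.
#' @return A [SignedGeneList-class].
#' @export
SignedGeneList <- function(contrast, genes, log2FC,
                           fdr = rep(0, length(genes)), info = NULL) {
  new("SignedGeneList", contrast = as.character(contrast),
      genes = as.character(genes), log2FC = as.numeric(log2FC),
      fdr = as.numeric(fdr), info = info)
}

#' Diet cohort design
#'
#' Describes the cohorts of a diet-switch longevity study: their diet
#' sequence, whether and when lipoic acid (LA) was supplemented, whether
#' the diet was switched mid-life, and the longevity class (extended or
#' baseline relative to the reference ad-libitum cohort).
#'
#' @slot design a `data.frame` with columns `cohort`, `longevityClass`
#'   (`"extended"` or `"baseline"`), `laSupplemented` (logical), `laPhase`
#'   (`"none"`, `"before"` or `"after"` the switch), `switched` (logical),
#'   `reference` (logical; exactly one `TRUE`) and `meanSurvivalDays`
#'   (numeric, may be `NA`; metadata only, never computed here).
#' @seealso [CohortDesign()], [defaultCohortDesign()].
#' @export
setClass("CohortDesign", representation(design = "data.frame"))

.validCohortDesign <- function(object) {
  d <- object@design
  need <- c("cohort", "longevityClass", "laSupplemented", "laPhase",
            "switched", "reference", "meanSurvivalDays")
  msg <- NULL
  if (!all(need %in% colnames(d)))
    msg <- c(msg, paste("design needs columns:",
                        paste(setdiff(need, colnames(d)), collapse = ", ")))
  else {
    if (sum(d$reference) != 1L)
      msg <- c(msg, "exactly one reference cohort is required")
    if (anyDuplicated(d$cohort)) msg <- c(msg, "cohort labels must be unique")
    if (!all(d$longevityClass %in% c("extended", "baseline")))
      msg <- c(msg, "longevityClass must be 'extended' or 'baseline'")
    if (!all(d$laPhase %in% c("none", "before", "after", "throughout")))
      msg <- c(msg, "laPhase must be none/before/after/throughout")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("CohortDesign", .validCohortDesign)

#' Construct a CohortDesign
#'
#' @param design data.frame as documented in [CohortDesign-class].
#' @return A [CohortDesign-class].
#' @export
CohortDesign <- function(design) new("CohortDesign", design = design)

#' The seven-cohort diet-switch design
#'
#' The standard design of the rat diet-switch study this package models:
#' ad libitum (AL, reference), caloric restriction (CR), LA-supplemented
#' AL (AL+LA), and the four mid-life switch cohorts (AL>CR, AL+LA>CR,
#' CR>AL, CR>AL+LA; switches at 12 months of age). CR, AL>CR and
#' CR>AL+LA are the long-lived ("extended") cohorts. Mean survival values
#' are carried as metadata only.
#'
#' @return A [CohortDesign-class] with seven cohorts.
#' @examples
#' defaultCohortDesign()
#' @export
defaultCohortDesign <- function() {
  CohortDesign(data.frame(
    cohort = c("AL", "AL>CR", "AL+LA>CR", "CR", "CR>AL", "CR>AL+LA",
               "AL+LA"),
    longevityClass = c("baseline", "extended", "baseline", "extended",
                       "baseline", "extended", "baseline"),
    laSupplemented = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    laPhase = c("none", "none", "before", "none", "none", "after",
                "throughout"),
    switched = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    reference = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    meanSurvivalDays = c(854, 1000, 859, 1025, 914, 1009, 858),
    stringsAsFactors = FALSE))
}

#' Planted simulation truth
#'
#' Records which genes were planted in which effect block and the full
#' per-gene, per-cohort log2 effect matrix, so downstream recoveries can
#' be scored exactly.
#'
#' @slot blocks named list of character vectors (disjoint gene id sets).
#' @slot effects numeric matrix, genes x cohorts, of planted log2 effects
#'   relative to the reference cohort (0 = no effect).
#' @slot geneIds all simulated gene ids, in matrix order.
#' @seealso [simulateCohortCounts()], [truthSignedList()].
#' @export
setClass("PlantedTruth",
         representation(blocks = "list", effects = "matrix",
                        geneIds = "character"))

.validPlantedTruth <- function(object) {
  msg <- NULL
  all_block <- unlist(object@blocks, use.names = FALSE)
  if (anyDuplicated(all_block))
    msg <- c(msg, "planted blocks must be disjoint")
  if (!all(all_block %in% object@geneIds))
    msg <- c(msg, "block genes must be simulated genes")
  if (!identical(rownames(object@effects), object@geneIds))
    msg <- c(msg, "effects rownames must equal geneIds")
  if (is.null(msg)) TRUE else msg
}
setValidity("PlantedTruth", .validPlantedTruth)

#' Species longevity network
#'
#' A per-species protein-protein interaction subnetwork built from a core
#' of longevity-associated genes (LAGs) and their first-order interaction
#' partners, restricted to the largest connected component of the PPI
#' graph.
#'
#' @slot species species label.
#' @slot graph the underlying `igraph` graph (the largest connected
#'   component of the input PPI).
#' @slot lagCore LAGs present in the component.
#' @slot partners first-order neighbours of the core, excluding the core.
#' @slot droppedLags LAGs that were present in the PPI but fell outside
#'   the largest connected component.
#' @seealso [buildLongevityNetwork()], [lagCore()], [partnerGenes()].
#' @export
setClass("LongevityNetwork",
         representation(species = "character", graph = "ANY",
                        lagCore = "character", partners = "character",
                        droppedLags = "character"))

.validLongevityNetwork <- function(object) {
  msg <- NULL
  nodes <- igraph::V(object@graph)$name
  if (length(intersect(object@lagCore, object@partners)))
    msg <- c(msg, "core and partners must be disjoint")
  if (!all(c(object@lagCore, object@partners) %in% nodes))
    msg <- c(msg, "core and partners must be component nodes")
  if (is.null(msg)) TRUE else msg
}
setValidity("LongevityNetwork", .validLongevityNetwork)

#' Cross-species ortholog map
#'
#' Source-to-target gene pairs with an inparalog confidence score in
#' `[0, 1]`; pairs below the score threshold are excluded at mapping time
#' (see [mapOrthologs()]).
#'
#' @slot speciesFrom,speciesTo species labels.
#' @slot pairs `data.frame` with columns `source`, `target`, `score`.
#' @export
setClass("OrthologMap",
         representation(speciesFrom = "character", speciesTo = "character",
                        pairs = "data.frame"))

.validOrthologMap <- function(object) {
  p <- object@pairs
  msg <- NULL
  if (!all(c("source", "target", "score") %in% colnames(p)))
    msg <- c(msg, "pairs needs columns source, target, score")
  else {
    if (nrow(p) && (any(p$score < 0 | p$score > 1)))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (anyDuplicated(p[c("source", "target")]))
      msg <- c(msg, "pairs must be unique")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("OrthologMap", .validOrthologMap)

#' Construct an OrthologMap
#' @param pairs data.frame with columns `source`, `target`, `score`.
#' @param speciesFrom,speciesTo species labels.
#' @return An [OrthologMap-class].
#' @export
OrthologMap <- function(pairs, speciesFrom = "a", speciesTo = "b") {
  new("OrthologMap", speciesFrom = speciesFrom, speciesTo = speciesTo,
      pairs = as.data.frame(pairs))
}

#' One-tailed overlap enrichment result
#'
#' The 2x2 contingency counts of a query/target overlap over a declared
#' gene universe, with the one-tailed (enrichment) Fisher p-value, i.e.
#' the hypergeometric upper tail P(X >= k).
#'
#' @slot k overlap count; @slot q query size; @slot t target size;
#' @slot u universe size; @slot p one-tailed p-value in (0, 1].
#' @seealso [fisherOverlap()].
#' @export
setClass("OverlapResult",
         representation(k = "integer", q = "integer", t = "integer",
                        u = "integer", p = "numeric"))

.validOverlapResult <- function(object) {
  msg <- NULL
  if (object@k > min(object@q, object@t))
    msg <- c(msg, "k cannot exceed min(q, t)")
  if (object@q > object@u || object@t > object@u)
    msg <- c(msg, "q and t cannot exceed the universe size")
  if (object@p <= 0 || object@p > 1 + 1e-12)
    msg <- c(msg, "p must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
}
setValidity("OverlapResult", .validOverlapResult)

#' qPCR assay measurements for one target gene in one group
#'
#' Replicate Ct values for a target gene plus the replicate Ct values of a
#' reference-gene panel, together with the amplification efficiency of the
#' target assay expressed as the per-cycle amplification factor E
#' (E = 2 corresponds to 100 % efficiency).
#'
#' @slot targetName target gene name.
#' @slot targetCt numeric replicate Ct values of the target.
#' @slot referenceCts named list of numeric replicate Ct vectors, one per
#'   reference gene.
#' @slot efficiency amplification factor E in (1, 2.2].
#' @slot group group label (e.g. `"CR"` or `"AL"`).
#' @seealso [QpcrAssay()], [deltaDeltaCt()].
#' @export
setClass("QpcrAssay",
         representation(targetName = "character", targetCt = "numeric",
                        referenceCts = "list", efficiency = "numeric",
                        group = "character"))

.validQpcrAssay <- function(object) {
  msg <- NULL
  cts <- c(object@targetCt, unlist(object@referenceCts))
  if (!length(object@targetCt)) msg <- c(msg, "need >= 1 target Ct replicate")
  if (!length(object@referenceCts) || is.null(names(object@referenceCts)))
    msg <- c(msg, "need >= 1 named reference gene")
  if (any(!is.finite(cts)) || any(cts <= 0))
    msg <- c(msg, "Ct values must be positive and finite")
  if (length(object@efficiency) != 1 || object@efficiency <= 1 ||
      object@efficiency > 2.2)
    msg <- c(msg, "efficiency must be a single factor in (1, 2.2]")
  if (is.null(msg)) TRUE else msg
}
setValidity("QpcrAssay", .validQpcrAssay)

#' Construct a QpcrAssay
#'
#' @param targetName target gene name.
#' @param targetCt replicate Ct values.
#' @param referenceCts named list of reference-gene replicate Ct vectors.
#' @param efficiency amplification factor E in (1, 2.2]; use
#'   [percentToEfficiency()] to convert percent efficiencies.
#' @param group group label.
#' @return A [QpcrAssay-class].
#' @export
QpcrAssay <- function(targetName, targetCt, referenceCts, efficiency = 2,
                      group = NA_character_) {
  new("QpcrAssay", targetName = targetName,
      targetCt = as.numeric(targetCt), referenceCts = referenceCts,
      efficiency = efficiency, group = as.character(group))
}

#' Simulation parameters for the synthetic cohort study
#'
#' Defines the synthetic study: the cohort design, library replication,
#' the gene-wise mean and dispersion distributions, the planted effect
#' blocks and the library-size range. Gene-wise baseline means are
#' log-normal, dispersions gamma; both reflect typical bulk RNA-seq
#' ranges.
#'
#' @slot nGenes number of genes.
#' @slot design a [CohortDesign-class].
#' @slot samplesPerCohort libraries per cohort (default 3).
#' @slot baselineMeanLog,baselineMeanSdLog log-normal parameters of the
#'   gene baseline means (defaults `log(100)` and 1).
#' @slot dispersionShape,dispersionMean gamma parameters of the gene
#'   dispersions (defaults shape 2, mean 0.1).
#' @slot blocks named list of planted blocks; each element is a list with
#'   `size` (gene count), `cohorts` (labels carrying the effect) and
#'   `log2fc` (effect magnitude; the sign is drawn per gene and shared
#'   across that gene's cohorts).
#' @slot librarySizeRange range of the uniform library-size draw.
#' @slot seed default RNG seed for [simulateCohortCounts()].
#' @seealso [simParams()], [defaultBlocks()].
#' @export
setClass("SimulationParams",
         representation(nGenes = "integer", design = "CohortDesign",
                        samplesPerCohort = "integer",
                        baselineMeanLog = "numeric",
                        baselineMeanSdLog = "numeric",
                        dispersionShape = "numeric",
                        dispersionMean = "numeric",
                        blocks = "list", librarySizeRange = "numeric",
                        seed = "integer"))

.validSimulationParams <- function(object) {
  msg <- NULL
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@samplesPerCohort < 1L)
    msg <- c(msg, "samplesPerCohort must be positive")
  if (!nrow(object@design@design))
    msg <- c(msg, "cohort list must be non-empty")
  sizes <- vapply(object@blocks, function(b) as.numeric(b$size), 0)
  if (length(sizes) && sum(sizes) > object@nGenes)
    msg <- c(msg, "nGenes must be >= total planted block size")
  for (b in object@blocks) {
    if (!all(b$cohorts %in% object@design@design$cohort))
      msg <- c(msg, "block cohorts must exist in the design")
    if (!is.finite(b$log2fc))
      msg <- c(msg, "block effect sizes must be finite")
  }
  if (length(object@librarySizeRange) != 2 ||
      any(object@librarySizeRange <= 0))
    msg <- c(msg, "library sizes must be positive")
  if (object@dispersionMean < 0 || object@dispersionShape <= 0)
    msg <- c(msg, "dispersion parameters must be non-negative")
  if (is.null(msg)) TRUE else msg
}
setValidity("SimulationParams", .validSimulationParams)
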