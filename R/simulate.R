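#' Default planted effect blocks
#'
#' The block structure mirrors the biology the cohort algebra is designed
#' to disentangle:
#' \describe{
#'   \item{shared_CR_LA}{DE with a common sign in every non-reference
#'     cohort (the "neuroprotective profile" analogue).}
#'   \item{longevity}{DE only in the extended-longevity cohorts
#'     (CR, AL>CR, CR>AL+LA).}
#'   \item{dietary_memory}{DE only in the CR>AL+LA cohort (LA after the
#'     switch retains CR-like longevity).}
#'   \item{LA_confounder}{DE in every LA-supplemented cohort regardless of
#'     longevity (AL+LA, AL+LA>CR, CR>AL+LA).}
#'   \item{switch_confounder}{DE in every switched cohort (AL>CR,
#'     AL+LA>CR, CR>AL, CR>AL+LA).}
#' }
#' Remaining genes form the null background.
#'
#' @param size genes per block.
#' @param log2fc planted effect magnitude (sign drawn per gene).
#' @param include character vector of block names to keep.
#' @return named list of block specifications for [simParams()].
#' @export
defaultBlocks <- function(size = 100, log2fc = 2,
                          include = c("shared_CR_LA", "longevity",
                                      "dietary_memory", "LA_confounder",
                                      "switch_confounder")) {
  all <- list(
    shared_CR_LA = list(size = size, log2fc = log2fc,
      cohorts = c("CR", "AL+LA", "AL>CR", "AL+LA>CR", "CR>AL", "CR>AL+LA")),
    longevity = list(size = size, log2fc = log2fc,
      cohorts = c("CR", "AL>CR", "CR>AL+LA")),
    dietary_memory = list(size = size, log2fc = log2fc,
      cohorts = "CR>AL+LA"),
    LA_confounder = list(size = size, log2fc = log2fc,
      cohorts = c("AL+LA", "AL+LA>CR", "CR>AL+LA")),
    switch_confounder = list(size = size, log2fc = log2fc,
      cohorts = c("AL>CR", "AL+LA>CR", "CR>AL", "CR>AL+LA")))
  all[intersect(names(all), include)]
}

#' Construct simulation parameters
#'
#' Defaults emulate the seven-cohort diet-switch study at desk scale:
#' 10,000 genes, three libraries per cohort, log-normal(log 100, 1) gene
#' means, gamma(shape 2, mean 0.1) dispersions and library sizes uniform
#' in 0.5-1.5 million reads.
#'
#' @param nGenes number of genes.
#' @param design a [CohortDesign-class] (default [defaultCohortDesign()]).
#' @param samplesPerCohort libraries per cohort.
#' @param baselineMeanLog,baselineMeanSdLog log-normal parameters of the
#'   baseline gene means.
#' @param dispersionShape,dispersionMean gamma parameters of the gene-wise
#'   NB dispersions; `dispersionMean = 0` gives Poisson counts.
#' @param blocks planted blocks, see [defaultBlocks()]; `list()` for a
#'   pure null simulation.
#' @param librarySizeRange range of the uniform library-size draw.
#' @param seed default seed used by [simulateCohortCounts()].
#' @return A [SimulationParams-class].
#' @examples
#' p <- simParams(nGenes = 500, blocks = defaultBlocks(size = 10))
#' sim <- simulateCohortCounts(p, seed = 1)
#' sim$counts
#' @export
simParams <- function(nGenes = 10000, design = defaultCohortDesign(),
                      samplesPerCohort = 3,
                      baselineMeanLog = log(100), baselineMeanSdLog = 1,
                      dispersionShape = 2, dispersionMean = 0.1,
                      blocks = defaultBlocks(),
                      librarySizeRange = c(0.5e6, 1.5e6), seed = 1L) {
  new("SimulationParams", nGenes = as.integer(nGenes), design = design,
      samplesPerCohort = as.integer(samplesPerCohort),
      baselineMeanLog = baselineMeanLog,
      baselineMeanSdLog = baselineMeanSdLog,
      dispersionShape = dispersionShape, dispersionMean = dispersionMean,
      blocks = blocks, librarySizeRange = as.numeric(librarySizeRange),
      seed = as.integer(seed))
}

#' Simulate a cohort count matrix with planted truth
#'
#' Draws gene-wise baseline means (log-normal) and dispersions (gamma),
#' assigns planted blocks to the leading gene indices, gives every planted
#' gene a random effect sign shared across its block cohorts, and draws
#' counts for sample `s` in cohort `c` as
#' `NB(mean = mu_g * 2^effect[g, c] * L_s / sum(mu), size = 1/phi_g)`,
#' where `L_s` is the sample library-size draw. A zero dispersion yields
#' Poisson counts. Identical `params` and `seed` give bit-identical
#' output.
#'
#' @param params a [SimulationParams-class].
#' @param seed integer seed (defaults to the seed stored in `params`).
#' @return list with elements `counts` (a [CohortCountSet-class]) and
#'   `truth` (a [PlantedTruth-class]).
#' @export
simulateCohortCounts <- function(params, seed = params@seed) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  d <- params@design@design
  if (!nrow(d)) stop("cohort list is empty")
  if (any(params@librarySizeRange <= 0))
    stop("library sizes must be positive")
  set.seed(seed)

  nG <- params@nGenes
  genes <- sprintf("rgene_%05d", seq_len(nG))
  cohortsv <- d$cohort
  mu <- rlnorm(nG, params@baselineMeanLog, params@baselineMeanSdLog)
  phi <- if (params@dispersionMean > 0)
    rgamma(nG, shape = params@dispersionShape,
           scale = params@dispersionMean / params@dispersionShape)
  else rep(0, nG)

  effects <- matrix(0, nG, length(cohortsv),
                    dimnames = list(genes, cohortsv))
  blocks <- list()
  at <- 0L
  for (bn in names(params@blocks)) {
    b <- params@blocks[[bn]]
    idx <- at + seq_len(b$size)
    at <- at + as.integer(b$size)
    signs <- sample(c(-1, 1), b$size, replace = TRUE)
    for (co in b$cohorts) effects[idx, co] <- signs * b$log2fc
    blocks[[bn]] <- genes[idx]
  }

  nS <- params@samplesPerCohort
  sampCohort <- rep(cohortsv, each = nS)
  samples <- paste0(gsub("[^A-Za-z0-9]+", "", sampCohort), "_",
                    rep(seq_len(nS), times = length(cohortsv)))
  samples <- make.unique(samples, sep = "_")
  libs <- runif(length(samples), params@librarySizeRange[1],
                params@librarySizeRange[2])
  sumMu <- sum(mu)

  counts <- matrix(0L, nG, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mj <- mu * 2^effects[, sampCohort[j]] * libs[j] / sumMu
    counts[, j] <- if (params@dispersionMean > 0)
      rnbinom(nG, size = 1 / phi, mu = mj) else rpois(nG, mj)
  }

  truth <- new("PlantedTruth", blocks = blocks, effects = effects,
               geneIds = genes)
  list(counts = CohortCountSet(counts, cohort = sampCohort),
       truth = truth)
}

#' Expected signed DE list implied by the planted truth
#'
#' The genes whose planted effect in `cohort` is non-zero, signed by the
#' planted effect — the ground-truth counterpart of a [callDE()] result
#' for the cohort-vs-reference contrast.
#'
#' @param truth a [PlantedTruth-class].
#' @param cohort cohort label.
#' @param contrast contrast name for the returned list (default
#'   `"<cohort>_vs_ref"`).
#' @return A [SignedGeneList-class].
#' @export
truthSignedList <- function(truth, cohort,
                            contrast = paste0(cohort, "_vs_ref")) {
  if (!cohort %in% colnames(truth@effects))
    stop("unknown cohort: ", cohort)
  e <- truth@effects[, cohort]
  keep <- e != 0
  SignedGeneList(contrast, truth@geneIds[keep], e[keep])
}

#' Simulate a PPI network containing a planted LAG core
#'
#' Erdos-Renyi edge draw over species-prefixed node ids with a uniformly
#' random LAG subset, used as a fixture for longevity-network
#' construction.
#'
#' @param nNodes number of nodes.
#' @param nLags number of LAG nodes (must not exceed `nNodes`).
#' @param edgeProb edge probability in (0, 1].
#' @param seed integer seed.
#' @param species species prefix for node ids.
#' @return list with elements `graph` (undirected `igraph`) and `lags`
#'   (character vector of LAG node ids).
#' @export
simulatePPIWithLAGs <- function(nNodes, nLags, edgeProb, seed = 1L,
                                species = "mouse") {
  if (nLags > nNodes) stop("nLags cannot exceed nNodes")
  if (edgeProb < 0 || edgeProb > 1) stop("edgeProb must lie in [0, 1]")
  set.seed(seed)
  nodes <- sprintf("%s_g%04d", species, seq_len(nNodes))
  g <- if (nNodes >= 2) {
    pairs <- utils::combn(nodes, 2)
    keep <- runif(ncol(pairs)) < edgeProb
    igraph::graph_from_data_frame(
      data.frame(from = pairs[1, keep], to = pairs[2, keep]),
      directed = FALSE, vertices = nodes)
  } else igraph::make_empty_graph(n = nNodes, directed = FALSE)
  if (nNodes < 2) igraph::V(g)$name <- nodes
  lags <- sort(sample(nodes, nLags))
  list(graph = g, lags = lags)
}

#' Simulate a cross-species ortholog map with inparalogs
#'
#' A fraction `fracMapped` of the source genes receives a one-to-one
#' primary pair (score 1). A fraction `fracInparalog` of those mapped
#' genes additionally receives a secondary pair with a sub-threshold
#' inparalog score, to exercise inparalog exclusion in
#' [mapOrthologs()].
#'
#' @param genesA source-species gene ids.
#' @param genesB target-species gene ids.
#' @param fracMapped fraction of `genesA` with a primary ortholog.
#' @param fracInparalog fraction of mapped genes with a sub-threshold
#'   secondary pair.
#' @param seed integer seed.
#' @param scoreThreshold the inparalog threshold the secondary pairs fall
#'   below (default 0.05).
#' @param speciesFrom,speciesTo species labels.
#' @return An [OrthologMap-class].
#' @export
simulateOrthologMap <- function(genesA, genesB, fracMapped = 0.7,
                                fracInparalog = 0.1, seed = 1L,
                                scoreThreshold = 0.05,
                                speciesFrom = "rat", speciesTo = "mouse") {
  if (!length(genesA) || !length(genesB)) stop("gene lists must be non-empty")
  if (fracMapped < 0 || fracMapped > 1 || fracInparalog < 0 ||
      fracInparalog > 1)
    stop("fractions must lie in [0, 1]")
  set.seed(seed)
  nMap <- round(fracMapped * length(genesA))
  src <- sample(genesA, nMap)
  ## one-to-one where the target space allows it, many-to-one otherwise
  tgt <- if (nMap <= length(genesB)) sample(genesB, nMap)
         else sample(genesB, nMap, replace = TRUE)
  pairs <- data.frame(source = src, target = tgt, score = rep(1, nMap),
                      stringsAsFactors = FALSE)
  nIn <- round(fracInparalog * nMap)
  if (nIn > 0) {
    inSrc <- sample(src, nIn)
    spare <- setdiff(genesB, tgt)
    inTgt <- if (length(spare) >= nIn) sample(spare, nIn)
             else sample(genesB, nIn)
    extra <- data.frame(source = inSrc, target = inTgt,
                        score = runif(nIn, 0, scoreThreshold * 0.999),
                        stringsAsFactors = FALSE)
    extra <- extra[extra$source != "" &
                     !duplicated(paste(extra$source, extra$target)), ]
    key <- paste(extra$source, extra$target)
    pairs <- rbind(pairs,
                   extra[!key %in% paste(pairs$source, pairs$target), ])
  }
  rownames(pairs) <- NULL
  OrthologMap(pairs, speciesFrom, speciesTo)
}
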