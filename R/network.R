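#' Largest connected component of a PPI graph
#'
#' Returns the subgraph induced by the nodes of the largest connected
#' component. Ties in component size are broken deterministically by the
#' component containing the lexicographically smallest node name.
#'
#' @param graph an undirected `igraph` graph with named vertices and at
#'   least one edge.
#' @return the induced `igraph` subgraph.
#' @export
largestConnectedComponent <- function(graph) {
  if (igraph::vcount(graph) == 0 || igraph::ecount(graph) == 0)
    stop("network is empty")
  comp <- igraph::components(graph)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    nm <- igraph::V(graph)$name
    firstNode <- vapply(big, function(k) min(nm[comp$membership == k]), "")
    big <- big[order(firstNode)][1]
  }
  igraph::induced_subgraph(graph,
                           which(comp$membership == big))
}

#' Build a species longevity network
#'
#' Restricts the PPI graph to its largest connected component, takes the
#' LAGs present in that component as the core and their first-order
#' neighbours (excluding the core) as partners. LAGs present in the PPI
#' but outside the largest component are reported in the `droppedLags`
#' slot rather than silently discarded; LAGs absent from the PPI
#' altogether are reported via a message.
#'
#' @param graph an undirected `igraph` PPI graph with named vertices.
#' @param lags character vector of LAG gene ids (non-empty).
#' @param species species label.
#' @return A [LongevityNetwork-class].
#' @export
buildLongevityNetwork <- function(graph, lags, species = "species") {
  if (!length(lags)) stop("LAG set is empty")
  allNodes <- igraph::V(graph)$name
  inPpi <- intersect(lags, allNodes)
  if (!length(inPpi))
    stop("no LAG is present in the PPI network")
  absent <- setdiff(lags, allNodes)
  if (length(absent))
    message(length(absent), " LAG(s) absent from the PPI were ignored")
  lcc <- largestConnectedComponent(graph)
  nodes <- igraph::V(lcc)$name
  core <- intersect(inPpi, nodes)
  dropped <- setdiff(inPpi, nodes)
  if (!length(core))
    stop("no LAG falls inside the largest connected component")
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(lcc, core),
                             function(v) v$name)))
  partners <- setdiff(nb, core)
  new("LongevityNetwork", species = species, graph = lcc,
      lagCore = sort(core), partners = sort(partners),
      droppedLags = sort(dropped))
}

#' Map genes across species through an ortholog table
#'
#' Returns the union of target genes over all pairs whose score is at or
#' above `minScore` (inclusive; sub-threshold pairs are the excluded
#' inparalogs) and whose source gene is in the query. Unmapped query
#' genes are reported in the `"unmapped"` attribute.
#'
#' @param genes character vector of source-species gene ids.
#' @param map an [OrthologMap-class].
#' @param minScore inparalog score threshold in `[0, 1]` (default 0.05).
#' @return character vector of target-species gene ids, with attribute
#'   `unmapped` listing query genes without a retained pair.
#' @export
mapOrthologs <- function(genes, map, minScore = 0.05) {
  if (minScore < 0 || minScore > 1) stop("minScore must lie in [0, 1]")
  p <- map@pairs[map@pairs$score >= minScore, , drop = FALSE]
  hit <- p$source %in% genes
  out <- sort(unique(p$target[hit]))
  attr(out, "unmapped") <- setdiff(genes, p$source[hit])
  out
}

.hyperUpperTail <- function(k, q, t, u) {
  ## P(X >= k) for X ~ Hypergeometric(universe u, target t, draws q),
  ## by direct summation of the probability terms.
  if (k <= 0) return(1)
  i <- k:min(q, t)
  lterm <- lchoose(t, i) + lchoose(u - t, q - i) - lchoose(u, q)
  min(1, sum(exp(lterm)))
}

#' One-tailed Fisher overlap test of two gene sets
#'
#' Exact enrichment test of the overlap between a query and a target set
#' within a declared universe: the hypergeometric upper tail
#' `P(X >= k)` computed by direct term summation (no chi-square
#' approximation). Both sets must be subsets of the universe.
#'
#' @param query,target,universe character vectors of gene ids; `query`
#'   and `target` must be subsets of `universe`.
#' @return An [OverlapResult-class] carrying the 2x2 counts and the
#'   p-value.
#' @examples
#' u <- paste0("g", 1:100)
#' fisherOverlap(u[1:5], u[3:12], u)
#' @export
fisherOverlap <- function(query, target, universe) {
  if (!length(universe)) stop("universe is empty")
  query <- unique(query); target <- unique(target)
  universe <- unique(universe)
  badQ <- setdiff(query, universe)
  badT <- setdiff(target, universe)
  if (length(badQ) || length(badT))
    stop("sets must be subsets of the universe; offending ids: ",
         paste(head(c(badQ, badT), 10), collapse = ", "))
  k <- length(intersect(query, target))
  new("OverlapResult", k = as.integer(k), q = length(query),
      t = length(target), u = length(universe),
      p = .hyperUpperTail(k, length(query), length(target),
                          length(universe)))
}

#' Cross-species overlap report for a query gene set
#'
#' For each species, maps the query and the universe into that species
#' through its ortholog table and tests the overlap against the LAG core
#' and the partner set separately. A pooled test is run in the source
#' (query) gene space against the genes that back-map into any species'
#' core-or-partner set.
#'
#' Universe policies: `"expressed_mappable"` (default) restricts the
#' pooled universe to source genes mappable to at least one species;
#' `"expressed"` keeps the full source universe for the pooled test
#' (unmappable genes count as non-target); `"network_nodes"` uses each
#' species' component nodes as that species' universe. Per-species tests
#' are identical under the first two policies, since mapping itself
#' defines the species-space universe.
#'
#' @param query character vector of source-species gene ids.
#' @param networks named list of [LongevityNetwork-class], one per
#'   species.
#' @param maps named list of [OrthologMap-class], one per species (source
#'   species to that species).
#' @param universe character vector of source-species gene ids (e.g. all
#'   expressed genes); the query must be a subset.
#' @param universePolicy see Details.
#' @param minScore inparalog score threshold for [mapOrthologs()].
#' @return list with `species` (data.frame: species, set, k, q, t, u, p),
#'   `pooled` (an [OverlapResult-class]) and `pooledK` (the pooled
#'   overlap count).
#' @export
speciesOverlapReport <- function(query, networks, maps, universe,
                                 universePolicy = c("expressed_mappable",
                                                    "expressed",
                                                    "network_nodes"),
                                 minScore = 0.05) {
  universePolicy <- match.arg(universePolicy)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  sp <- names(networks)
  if (is.null(sp) || !all(sp %in% names(maps)))
    stop("each species needs a network and an ortholog map")

  rows <- list()
  pooledTarget <- character()
  mappableAny <- character()
  for (s in sp) {
    net <- networks[[s]]
    mp <- maps[[s]]
    uniS <- mapOrthologs(universe, mp, minScore)
    mappedQ <- mapOrthologs(intersect(query, universe), mp, minScore)
    if (universePolicy == "network_nodes") {
      nodes <- componentNodes(net)
      uniS <- nodes
      mappedQ <- intersect(mappedQ, nodes)
    }
    if (!length(uniS))
      stop("universe policy unsatisfiable: no mappable universe for ", s)
    coreS <- intersect(lagCore(net), uniS)
    partS <- intersect(partnerGenes(net), uniS)
    for (set in c("core", "partners")) {
      tgt <- if (set == "core") coreS else partS
      r <- fisherOverlap(intersect(mappedQ, uniS), tgt, uniS)
      rows[[paste(s, set)]] <- data.frame(
        species = s, set = set, k = r@k, q = r@q, t = r@t, u = r@u,
        p = r@p, stringsAsFactors = FALSE)
    }
    ## back-map: source genes with >= 1 retained pair into core/partners
    keepPairs <- mp@pairs[mp@pairs$score >= minScore, , drop = FALSE]
    member <- union(lagCore(net), partnerGenes(net))
    pooledTarget <- union(pooledTarget,
                          keepPairs$source[keepPairs$target %in% member])
    mappableAny <- union(mappableAny, keepPairs$source)
  }
  pooledU <- switch(universePolicy,
                    expressed_mappable = intersect(universe, mappableAny),
                    expressed = universe,
                    network_nodes = intersect(universe, mappableAny))
  pooled <- fisherOverlap(intersect(query, pooledU),
                          intersect(pooledTarget, pooledU), pooledU)
  list(species = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pooled = pooled, pooledK = pooled@k)
}

#' Over-representation analysis of a gene-set collection
#'
#' One [fisherOverlap()] test per set, BH-adjusted across sets. Sets are
#' intersected with the universe before testing (the usual ORA
#' convention for externally curated collections).
#'
#' @param query character vector of gene ids (subset of the universe).
#' @param sets named list of character vectors.
#' @param universe character vector of gene ids.
#' @return data.frame with columns `set`, `k`, `q`, `t`, `u`, `p`, `fdr`,
#'   ordered as the input collection.
#' @export
oraEnrichment <- function(query, sets, universe) {
  if (!length(sets)) stop("gene-set collection is empty")
  if (is.null(names(sets))) stop("sets must be named")
  res <- lapply(sets, function(s)
    as.data.frame(fisherOverlap(query, intersect(s, universe), universe)))
  tab <- do.call(rbind, res)
  tab <- data.frame(set = names(sets), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$fdr <- bhAdjust(tab$p)
  tab
}
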