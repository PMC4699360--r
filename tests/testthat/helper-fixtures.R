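## Shared fixtures and independent oracles. Oracles here are deliberately
## naive (brute force / enumeration) and never share code with the
## implementation they check.

twoCohortDesign <- function() {
  CohortDesign(data.frame(
    cohort = c("AL", "CR"),
    longevityClass = c("baseline", "extended"),
    laSupplemented = FALSE, laPhase = "none", switched = FALSE,
    reference = c(TRUE, FALSE), meanSurvivalDays = NA_real_))
}

## a count matrix whose columns sum to exactly 1e6, so CPM == count for
## the non-filler genes
cpmExactMatrix <- function(rows) {
  m <- do.call(rbind, rows)
  filler <- 1e6 - colSums(m)
  stopifnot(all(filler >= 0))
  out <- rbind(m, filler = filler)
  rownames(out) <- c(names(rows), "filler")
  colnames(out) <- paste0("s", seq_len(ncol(out)))
  out
}

randomSignedList <- function(genes, n, contrast, seed) {
  set.seed(seed)
  g <- sample(genes, n)
  fc <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 3)
  SignedGeneList(contrast, g, fc)
}

## brute-force BH: q_(i) = min over j >= i of (m/j) p_(j)
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(sp[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

## hypergeometric upper tail by direct choose() enumeration
hyperEnumOracle <- function(k, q, t, u) {
  if (k <= 0) return(1)
  tot <- 0
  for (i in k:min(q, t))
    tot <- tot + choose(t, i) * choose(u - t, q - i) / choose(u, q)
  min(1, tot)
}

## connected components by hand-rolled BFS over an edge data.frame
bfsComponents <- function(edges, nodes) {
  adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                function(x) character())
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character()
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n
    comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

randomGraph <- function(nNodes, edgeProb, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(nNodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- runif(nrow(pairs)) < edgeProb
  list(nodes = nodes,
       edges = data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                          stringsAsFactors = FALSE),
       graph = igraph::graph_from_data_frame(
         data.frame(pairs[keep, 1], pairs[keep, 2]),
         directed = FALSE, vertices = nodes))
}

## small cross-species overlap fixture with a query enriched for
## longevity-network membership (enrichFold = 1 gives a null query)
overlapFixture <- function(seed, nUniverse = 1000, nQuery = 50,
                           enrichFold = 5) {
  universe <- sprintf("rgene_%05d", seq_len(nUniverse))
  species <- c("mouse", "fly", "worm")
  networks <- list(); maps <- list()
  for (j in seq_along(species)) {
    s <- species[j]
    ppi <- simulatePPIWithLAGs(800, 25, 0.004, seed = seed * 10 + j,
                               species = s)
    networks[[s]] <- buildLongevityNetwork(ppi$graph, ppi$lags, s)
    maps[[s]] <- simulateOrthologMap(universe,
                                     igraph::V(ppi$graph)$name,
                                     0.7, 0.1, seed = seed * 100 + j,
                                     speciesFrom = "rat", speciesTo = s)
  }
  member <- unique(unlist(lapply(species, function(s) {
    kp <- maps[[s]]@pairs[maps[[s]]@pairs$score >= 0.05, ]
    tgt <- union(lagCore(networks[[s]]), partnerGenes(networks[[s]]))
    kp$source[kp$target %in% tgt]
  })))
  member <- intersect(member, universe)
  set.seed(seed + 5000)
  query <- sample(universe, nQuery,
                  prob = ifelse(universe %in% member, enrichFold, 1))
  list(universe = universe, networks = networks, maps = maps,
       query = query, member = member)
}

## per-contrast signed lists implied directly by the planted truth
truthContrasts <- function(truth, design) {
  cohorts <- setdiff(cohortLabels(design), referenceCohort(design))
  out <- lapply(cohorts, function(co) truthSignedList(truth, co))
  names(out) <- cohorts
  out
}
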