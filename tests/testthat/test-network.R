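test_that("largest connected component matches a BFS oracle", {
  single <- igraph::graph_from_data_frame(data.frame("a", "b"),
                                          directed = FALSE)
  expect_setequal(igraph::V(largestConnectedComponent(single))$name,
                  c("a", "b"))

  ## components of size 5 and 3
  ed <- data.frame(a = c("a1", "a2", "a3", "a4", "b1", "b2"),
                   b = c("a2", "a3", "a4", "a5", "b2", "b3"))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  expect_setequal(igraph::V(largestConnectedComponent(g))$name,
                  paste0("a", 1:5))

  ## size tie: the component holding the lexicographically smallest node
  tie <- igraph::graph_from_data_frame(
    data.frame(a = c("z1", "z2", "z3", "a1", "a2", "a3"),
               b = c("z2", "z3", "z4", "a2", "a3", "a4")),
    directed = FALSE)
  expect_setequal(igraph::V(largestConnectedComponent(tie))$name,
                  paste0("a", 1:4))

  for (i in 1:30) {
    rg <- randomGraph(25, 0.06, seed = 700 + i)
    if (nrow(rg$edges) == 0) next
    comps <- bfsComponents(rg$edges, rg$nodes)
    sizes <- vapply(comps, length, 0L)
    big <- comps[sizes == max(sizes)]
    expected <- big[[order(vapply(big, min, ""))[1]]]
    expect_setequal(igraph::V(largestConnectedComponent(rg$graph))$name,
                    expected)
  }
  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_error(largestConnectedComponent(empty), "empty")
})

test_that("longevity networks take cores and first-order partners", {
  star <- igraph::graph_from_data_frame(
    data.frame(a = "hub", b = paste0("leaf", 1:5)), directed = FALSE)
  net <- buildLongevityNetwork(star, "hub", species = "toy")
  expect_identical(lagCore(net), "hub")
  expect_setequal(partnerGenes(net), paste0("leaf", 1:5))

  ## LAG isolated in a smaller component is dropped but reported
  g2 <- igraph::graph_from_data_frame(
    data.frame(a = c("a1", "a2", "a3", "m1"),
               b = c("a2", "a3", "a4", "m2")), directed = FALSE)
  net2 <- buildLongevityNetwork(g2, c("a1", "m1"))
  expect_identical(lagCore(net2), "a1")
  expect_identical(net2@droppedLags, "m1")
  expect_error(buildLongevityNetwork(g2, "absent"), "no LAG")

  ## adjacency oracle on random graphs + idempotence on own component
  for (i in 1:10) {
    rg <- randomGraph(30, 0.08, seed = 710 + i)
    if (nrow(rg$edges) == 0) next
    lcc <- largestConnectedComponent(rg$graph)
    nodes <- igraph::V(lcc)$name
    set.seed(i)
    lags <- sample(nodes, min(4, length(nodes)))
    net <- buildLongevityNetwork(rg$graph, lags)
    nbr <- unique(unlist(lapply(lags, function(l)
      union(rg$edges$b[rg$edges$a == l], rg$edges$a[rg$edges$b == l]))))
    expect_setequal(partnerGenes(net), setdiff(intersect(nbr, nodes), lags))
    net2 <- buildLongevityNetwork(net@graph, lagCore(net))
    expect_setequal(componentNodes(net2), componentNodes(net))
    expect_setequal(lagCore(net2), lagCore(net))
  }
})

test_that("ortholog mapping respects the inparalog threshold and is monotone", {
  mp <- OrthologMap(data.frame(
    source = c("r1", "r1", "r2", "r3"),
    target = c("m1", "m2", "m3", "m4"),
    score = c(1, 0.04, 0.05, 0.6)))
  got <- mapOrthologs(c("r1", "r2"), mp)
  expect_setequal(got, c("m1", "m3"))          # 0.04 excluded, 0.05 kept
  expect_equal(length(mapOrthologs(character(), mp)), 0)
  expect_identical(attr(mapOrthologs(c("r1", "rX"), mp), "unmapped"), "rX")

  set.seed(73)
  sim <- simulateOrthologMap(paste0("r", 1:80), paste0("m", 1:150),
                             0.6, 0.3, seed = 73)
  q <- paste0("r", sample(1:80, 30))
  keep <- sim@pairs[sim@pairs$score >= 0.05, ]
  oracle <- sort(unique(keep$target[keep$source %in% q]))
  expect_identical(as.character(mapOrthologs(q, sim)), oracle)
  ## monotone: enlarging the query never shrinks the result
  expect_true(all(oracle %in% mapOrthologs(paste0("r", 1:80), sim)))
})

test_that("fisher overlap equals hypergeometric enumeration", {
  u <- paste0("g", 1:100)
  res <- fisherOverlap(u[1:5], u[3:12], u)
  expect_equal(res@k, 3)
  expect_equal(res@p, hyperEnumOracle(3, 5, 10, 100), tolerance = 1e-12)

  expect_equal(fisherOverlap(character(), u[1:10], u)@p, 1)
  expect_equal(fisherOverlap(u[1:10], u, u)@p, 1)
  expect_error(fisherOverlap(c(u[1], "zzz"), u[1:10], u), "zzz")

  ## super-uniformity under random queries: P(p < 0.05) stays near/under
  set.seed(74)
  target <- u[1:20]
  ps <- replicate(500, fisherOverlap(sample(u, 15), target, u)@p)
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("ORA wraps per-set fisher tests with BH correction", {
  u <- paste0("g", 1:60)
  sets <- list(self = u[1:10], other = u[30:45], mix = u[5:20])
  q <- u[1:10]
  tab <- oraEnrichment(q, sets, u)
  expect_equal(tab$p[tab$set == "self"], min(tab$p))
  for (i in seq_along(sets))
    expect_equal(tab$p[i], fisherOverlap(q, intersect(sets[[i]], u), u)@p)
  expect_equal(tab$fdr, bhAdjust(tab$p))
  emptyQ <- oraEnrichment(character(), sets, u)
  expect_true(all(emptyQ$p == 1))
  expect_error(oraEnrichment(q, list(), u), "empty")
})

test_that("species overlap report pools back-mapped memberships", {
  ## tiny deterministic fixture with disjoint species gene spaces
  u <- paste0("r", 1:40)
  mkNet <- function(edges, lags, sp)
    buildLongevityNetwork(igraph::graph_from_data_frame(edges,
                                                        directed = FALSE),
                          lags, species = sp)
  netA <- mkNet(data.frame(a = c("a1", "a1", "a3"),
                           b = c("a2", "a3", "a4")), "a1", "A")
  netB <- mkNet(data.frame(a = c("b1", "b2"), b = c("b2", "b3")), "b2", "B")
  mapA <- OrthologMap(data.frame(source = c("r1", "r2", "r3", "r4"),
                                 target = c("a1", "a2", "a9", "a4"),
                                 score = 1), "rat", "A")
  mapB <- OrthologMap(data.frame(source = c("r3", "r5", "r6"),
                                 target = c("b1", "b3", "b9"),
                                 score = 1), "rat", "B")
  rep <- speciesOverlapReport(c("r1", "r3", "r6"),
                              list(A = netA, B = netB),
                              list(A = mapA, B = mapB), u)
  ## members: A core+partners {a1,a2,a3} <- r1,r2 ; B {b1,b2,b3} <- r3,r5
  ## (a4 is a component node but neither core nor partner)
  expect_setequal(rep$pooled@k, 2)   # r1 (A member) + r3 (B member)
  expect_equal(rep$pooled@t, 4)
  ## universe policy: only mappable sources count
  expect_equal(rep$pooled@u, 6)
  expect_true(all(c("core", "partners") %in% rep$species$set))

  ## query disjoint from all networks: every p = 1, pooled k = 0
  disj <- speciesOverlapReport("r6", list(A = netA, B = netB),
                               list(A = mapA, B = mapB), u)
  expect_true(all(disj$species$p == 1))
  expect_equal(disj$pooledK, 0)
  expect_error(speciesOverlapReport("zz", list(A = netA),
                                    list(A = mapA), u), "subset")
})
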