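test_that("signed intersection demands direction agreement everywhere", {
  a <- SignedGeneList("a", c("g1", "g2", "g3"), c(1, -2, 0.5))
  b <- SignedGeneList("b", c("g1", "g2", "g4"), c(2, 2, 1))
  got <- signedIntersect(a, b)
  expect_identical(geneIds(got), "g1")
  expect_equal(got@log2FC, 1)            # carried from the first list
  expect_identical(geneIds(signedIntersect(a, a)), geneIds(a))

  set.seed(61)
  genes <- paste0("g", 1:100)
  ls <- lapply(1:3, function(i) randomSignedList(genes, 40, paste0("l", i),
                                                 seed = 600 + i))
  got <- signedIntersect(ls)
  sgn <- lapply(ls, directions)
  oracle <- Filter(function(g) {
    s <- vapply(sgn, function(x) x[g], c(g = 0))
    !anyNA(s) && length(unique(s)) == 1
  }, genes)
  expect_setequal(geneIds(got), oracle)
  expect_error(signedIntersect(a), "at least two")
})

test_that("signed subtraction removes only same-trend genes", {
  a <- SignedGeneList("a", "g1", 1.5)
  expect_identical(geneIds(signedSubtract(a, SignedGeneList("b", "g1", -1))),
                   "g1")
  expect_equal(length(signedSubtract(a, SignedGeneList("b", "g1", 2))), 0)

  set.seed(62)
  genes <- paste0("g", 1:100)
  x <- randomSignedList(genes, 50, "x", 71)
  y <- randomSignedList(genes, 50, "y", 72)
  got <- signedSubtract(x, y)
  sy <- directions(y)
  oracle <- geneIds(x)[vapply(seq_along(geneIds(x)), function(i) {
    g <- geneIds(x)[i]
    is.na(sy[g]) || sy[g] != sign(x@log2FC[i])
  }, TRUE)]
  expect_setequal(geneIds(got), oracle)

  ## symmetric difference: in exactly one list, or opposite-signed in both
  sd1 <- signedSymmetricDiff(x, y)
  oracle2 <- union(
    setdiff(geneIds(x), geneIds(y)[sy[geneIds(y)] ==
                                     directions(x)[geneIds(y)]]),
    setdiff(geneIds(y), geneIds(x)))
  both <- intersect(geneIds(x), geneIds(y))
  oppo <- both[directions(x)[both] != sy[both]]
  expect_setequal(geneIds(sd1),
                  union(union(setdiff(geneIds(x), both),
                              setdiff(geneIds(y), both)), oppo))
})

test_that("overlap percentage follows its arithmetic definition", {
  genes <- paste0("g", 1:400)
  shared <- genes[1:100]
  a <- SignedGeneList("a", c(shared, genes[101:200]), rep(1, 200))
  b <- SignedGeneList("b", c(shared, genes[301:350]), rep(1, 150))
  expect_equal(overlapPercentage(a, b, basis = "a"), 50)
  expect_equal(overlapPercentage(a, a), 100)
  disj <- SignedGeneList("d", genes[351:360], rep(1, 10))
  expect_equal(overlapPercentage(a, disj), 0)
  expect_equal(overlapPercentage(a, b, basis = "union"),
               100 * 100 / 250)
  empty <- SignedGeneList("e", character(), numeric())
  expect_error(overlapPercentage(empty, b), "empty")
})

test_that("shared profile recovers the planted block and is monotone", {
  des <- defaultCohortDesign()
  p <- simParams(nGenes = 400, blocks = defaultBlocks(size = 12),
                 librarySizeRange = c(1e5, 2e5))
  truth <- simulateCohortCounts(p, seed = 80)$truth
  contrasts <- truthContrasts(truth, des)
  prof <- sharedDietProfile(des, contrasts, c("CR", "AL+LA"))
  expect_setequal(geneIds(prof), plantedBlocks(truth)$shared_CR_LA)

  ## intersection monotonicity: adding cohorts never grows the profile
  sel2 <- c("CR", "AL+LA")
  for (extra in c("AL>CR", "AL+LA>CR", "CR>AL", "CR>AL+LA")) {
    sel2 <- c(sel2, extra)
    expect_true(all(geneIds(sharedDietProfile(des, contrasts, sel2)) %in%
                      geneIds(prof)))
  }

  ## an empty selected list empties the profile
  contrasts$CR <- SignedGeneList("CR_vs_ref", character(), numeric())
  expect_equal(length(sharedDietProfile(des, contrasts, c("CR", "AL+LA"))),
               0)
  expect_error(sharedDietProfile(des, contrasts, "CR"), "at least two")
})

test_that("dietary-memory derivation recovers its planted block exactly", {
  des <- defaultCohortDesign()
  memBlocks <- defaultBlocks(size = 12,
                             include = c("shared_CR_LA", "dietary_memory",
                                         "LA_confounder",
                                         "switch_confounder"))
  p <- simParams(nGenes = 400, blocks = memBlocks,
                 librarySizeRange = c(1e5, 2e5))
  truth <- simulateCohortCounts(p, seed = 81)$truth
  contrasts <- truthContrasts(truth, des)
  mem <- dietaryMemoryGenes(des, contrasts)
  expect_setequal(geneIds(mem), plantedBlocks(truth)$dietary_memory)
  expect_true(all(grepl("list1", mem@info$sources)))

  ## all contrasts empty -> empty result
  emptyC <- lapply(contrasts, function(x)
    SignedGeneList(contrastName(x), character(), numeric()))
  expect_equal(length(dietaryMemoryGenes(des, emptyC)), 0)

  ## a gene same-signed in the memory contrast and both confounders is
  ## excluded from List1 (and from the default combination)
  single <- list(
    "CR>AL+LA" = SignedGeneList("m", c("gA", "gB"), c(1, 1)),
    "AL+LA>CR" = SignedGeneList("c1", "gA", 1),
    "CR>AL" = SignedGeneList("c2", "gA", 1),
    "AL>CR" = SignedGeneList("s", character(), numeric()))
  got <- dietaryMemoryGenes(des, single)
  expect_false("gA" %in% geneIds(got))
  expect_true("gB" %in% geneIds(got))   # list1 + list3

  expect_error(dietaryMemoryGenes(des, contrasts[-1]),
               names(contrasts)[1])

  ## alternative combinations stay runnable
  expect_gte(length(dietaryMemoryGenes(des, contrasts,
                                       combine = "union")),
             length(mem))
  expect_lte(length(dietaryMemoryGenes(des, contrasts,
                                       combine = "intersect")),
             length(mem))
})

test_that("longevity derivation keeps extended-only, LA-free trends", {
  des <- defaultCohortDesign()
  p <- simParams(nGenes = 400, blocks = defaultBlocks(size = 12),
                 librarySizeRange = c(1e5, 2e5))
  truth <- simulateCohortCounts(p, seed = 82)$truth
  contrasts <- truthContrasts(truth, des)
  lon <- longevityGenes(des, contrasts)
  expect_setequal(geneIds(lon), plantedBlocks(truth)$longevity)
  expect_true(all(startsWith(colnames(lon@info), "log2FC_")))

  ## same trend in a baseline LA cohort excludes; opposite trend retains
  mini <- list(
    "CR" = SignedGeneList("CR", c("g1", "g2"), c(1, 1)),
    "AL>CR" = SignedGeneList("sw", c("g1", "g2"), c(1, 1)),
    "CR>AL+LA" = SignedGeneList("mem", c("g1", "g2"), c(1, 1)),
    "AL+LA" = SignedGeneList("la", c("g1", "g2"), c(1, -1)),
    "AL+LA>CR" = SignedGeneList("lasw", character(), numeric()))
  got <- longevityGenes(des, mini)
  expect_false("g1" %in% geneIds(got))  # same trend in AL+LA
  expect_true("g2" %in% geneIds(got))   # opposite trend retained
  expect_error(longevityGenes(des, mini[-1]), "CR")
})
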