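test_that("CPM is definitional and invertible", {
  m <- matrix(c(10, 999990, 0, 1e6), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- countsPerMillion(m)
  expect_equal(cpm["g1", "s1"], 10)
  expect_equal(cpm["g1", "s2"], 0)

  set.seed(1)
  r <- matrix(rpois(20, 30), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  got <- countsPerMillion(r)
  ## elementwise oracle
  for (j in 1:4) for (i in 1:5)
    expect_equal(got[i, j], r[i, j] * 1e6 / sum(r[, j]))
  ## inverse identity
  back <- sweep(got, 2, colSums(r) / 1e6, "*")
  expect_equal(back, r, tolerance = 1e-12, ignore_attr = TRUE)

  bad <- cbind(r, s5 = 0)
  expect_error(countsPerMillion(bad), "s5")
})

test_that("expression filter applies inclusive thresholds and matches a scan", {
  m <- cpmExactMatrix(list(
    boundary = c(1, 1, 1, 0, 0, 0),   # exactly 1 cpm in exactly 3 samples
    tooFew   = c(5, 5, 0, 0, 0, 0)))
  kept <- rownames(filterByExpression(m, minCpm = 1, minSamples = 3))
  expect_true("boundary" %in% kept)
  expect_false("tooFew" %in% kept)

  set.seed(7)
  r <- matrix(rpois(20 * 6, 3), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  kept <- rownames(filterByExpression(r))
  cpm <- countsPerMillion(r)
  oracle <- rownames(r)[vapply(seq_len(20), function(i)
    sum(cpm[i, ] >= 1) >= 3, TRUE)]
  expect_identical(kept, oracle)
  ## idempotence
  f1 <- filterByExpression(r)
  expect_identical(filterByExpression(f1), f1)
  expect_error(filterByExpression(r, minSamples = 7), "exceeds")
})

test_that("TMM factors are exact in degenerate cases and match edgeR", {
  base <- matrix(rpois(400, 50), 100, 4,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  same <- base[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  f <- tmmFactors(same)
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)
  ## pure depth difference: column B = 2 x column A
  depth <- cbind(s1 = base[, 1], s2 = 2 * base[, 1])
  fd <- tmmFactors(depth)
  expect_equal(unname(fd), c(1, 1), tolerance = 1e-12)
  expect_equal(prod(fd), 1, tolerance = 1e-12)

  skip_if_not_installed("edgeR")
  set.seed(21)
  m <- matrix(rnbinom(2000 * 4, mu = 100, size = 10), 2000, 4,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:4)))
  m[1:200, 2] <- rnbinom(200, mu = 800, size = 10)
  mine <- tmmFactors(m)
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_true(max(abs(mine / ref - 1)) < 0.02)
  expect_equal(prod(mine), 1, tolerance = 1e-12)
})

test_that("dispersion estimation recovers simulated values and shrinks", {
  set.seed(31)
  mkset <- function(size) {
    m <- matrix(if (is.finite(size)) rnbinom(2000 * 6, mu = 100, size = size)
                else rpois(2000 * 6, 100), 2000, 6,
                dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
    CohortCountSet(m, cohort = rep(c("A", "B"), each = 3))
  }
  dPois <- estimateNBDispersions(mkset(Inf))
  expect_lt(dPois$common, 0.05)
  d02 <- estimateNBDispersions(mkset(1 / 0.2))
  expect_gt(d02$common, 0.1)
  expect_lt(d02$common, 0.3)
  expect_true(all(d02$tagwise >= 0))

  ## a gene with identical counts in every sample carries no dispersion
  ## information: full shrinkage to (near) the common value
  x <- mkset(1 / 0.2)
  cnt <- SummarizedExperiment::assay(x, "counts")
  cnt["g1", ] <- 100L
  flat <- CohortCountSet(cnt, cohort = rep(c("A", "B"), each = 3))
  nf <- setNames(rep(1, 6), colnames(cnt))
  d <- estimateNBDispersions(flat, normFactors = nf)
  expect_lt(abs(log2(d$tagwise[["g1"]] / d$common)), 0.6)

  noRep <- CohortCountSet(cnt[, 1:2], cohort = c("A", "B"))
  expect_error(estimateNBDispersions(noRep), "fixed dispersion")
})

test_that("exact test is symmetric, central and Poisson-limited", {
  set.seed(41)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 10), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  x <- CohortCountSet(m, cohort = rep(c("A", "B"), each = 3))
  nf <- setNames(rep(1, 6), colnames(m))
  ab <- nbExactTest(x, "A", "B", dispersion = 0.1, normFactors = nf)
  ba <- nbExactTest(x, "B", "A", dispersion = 0.1, normFactors = nf)
  expect_equal(ab$PValue, ba$PValue, tolerance = 1e-12)
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)

  ## identical count vectors in the two groups: p = 1
  same <- m
  same[, 4:6] <- same[, 1:3]
  xs <- CohortCountSet(same, cohort = rep(c("A", "B"), each = 3))
  res <- nbExactTest(xs, "A", "B", dispersion = 0.1, normFactors = nf)
  expect_true(all(res$PValue == 1))
  expect_true(all(res$logFC == 0))

  ## dispersion -> 0 with equal library sizes: exact binomial test
  set.seed(42)
  for (r in 1:25) {
    cA <- rpois(3, 40); cB <- rpois(3, 40)
    p <- dietlong:::.condExactP(sum(cA), sum(cB), 3, 3, 0)
    tot <- sum(cA) + sum(cB)
    pb <- min(1, 2 * min(pbinom(sum(cB), tot, 0.5),
                         pbinom(sum(cB) - 1, tot, 0.5,
                                lower.tail = FALSE)))
    expect_equal(p, pb, tolerance = 1e-9)
  }
  expect_error(nbExactTest(x, "A", "missing"), "non-empty")
})

test_that("BH adjustment matches the step-up definition and oracles", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(51)
  for (r in 1:25) {
    p <- runif(sample(1:80, 1))
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    ## permutation invariance after order restoration
    perm <- sample(seq_along(p))
    expect_equal(bhAdjust(p[perm])[order(perm)], q, tolerance = 1e-12)
  }
})

test_that("DE calling uses strict thresholds and signs by fold change", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    logFC = c(1, -2, 0.5, 3),
                    FDR = c(0.05, 0.049, 0.01, 0.2))
  got <- callDE(tab, fdrCutoff = 0.05)
  expect_setequal(geneIds(got), c("b", "c"))
  expect_equal(unname(directions(got)[c("b", "c")]), c(-1L, 1L))
  empty <- callDE(tab[0, ])
  expect_equal(length(empty), 0)
})

test_that("the DE engine controls the null call rate", {
  des <- twoCohortDesign()
  frac <- numeric(3)
  for (i in 1:3) {
    p <- simParams(nGenes = 1000, design = des, blocks = list(),
                   dispersionMean = 0.1,
                   librarySizeRange = c(1.2e5, 2e5))
    sim <- simulateCohortCounts(p, seed = 400 + i)
    de <- contrastsVsReference(sim$counts, des)
    frac[i] <- length(de$lists$CR) / nrow(de$filtered)
  }
  expect_lt(mean(frac), 0.07)
})
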