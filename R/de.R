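.countMatrix <- function(x) {
  if (is(x, "CohortCountSet")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Counts per million
#'
#' Scales each library (column) to one million: entry `count * 1e6 /
#' library size`. Columns multiplied back by `libsize / 1e6` reproduce the
#' counts exactly.
#'
#' @param x a [CohortCountSet-class] or a count matrix.
#' @return numeric matrix of CPM values with the input dimnames.
#' @examples
#' countsPerMillion(matrix(c(10, 0), 2, 1,
#'                         dimnames = list(c("a", "b"), "s1")) * 1)
#' @export
countsPerMillion <- function(x) {
  cnt <- .countMatrix(x)
  lib <- colSums(cnt)
  if (any(lib <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(cnt)[lib <= 0], collapse = ", "))
  sweep(cnt, 2, lib / 1e6, "/")
}

#' Filter genes by expression level
#'
#' Retains exactly the genes with CPM at or above `minCpm` in at least
#' `minSamples` samples (both thresholds inclusive); gene order is
#' preserved. This is the standard "1 CPM in at least three samples"
#' expression filter applied before normalisation and testing.
#'
#' @param x a [CohortCountSet-class] or count matrix.
#' @param minCpm CPM threshold (default 1).
#' @param minSamples minimum number of samples meeting the threshold
#'   (default 3; must not exceed the sample count).
#' @return the input object restricted to the retained genes.
#' @export
filterByExpression <- function(x, minCpm = 1, minSamples = 3) {
  cnt <- .countMatrix(x)
  if (minSamples > ncol(cnt))
    stop("minSamples exceeds the number of samples")
  keep <- rowSums(countsPerMillion(cnt) >= minCpm) >= minSamples
  x[keep, ]
}

#' TMM normalisation factors
#'
#' Trimmed mean of M-values: for each sample a weighted trimmed mean of
#' gene-wise log2 ratios (M) against a reference sample, doubly trimmed
#' by M (default 30 %) and by average log2 expression A (default 5 %),
#' with inverse asymptotic-variance weights. Genes with a zero count in
#' either column are excluded from the trimmed mean. The reference sample
#' is the one whose upper-quartile CPM is closest to the mean upper
#' quartile. Factors are centred to a geometric mean of 1.
#'
#' @param x a [CohortCountSet-class] or count matrix with >= 2 samples.
#' @param trimM two-sided trim fraction on M values.
#' @param trimA two-sided trim fraction on A values.
#' @param refColumn optional reference sample index; chosen by the
#'   upper-quartile rule when `NULL`.
#' @return named numeric vector of per-sample normalisation factors with
#'   product 1.
#' @export
tmmFactors <- function(x, trimM = 0.30, trimA = 0.05, refColumn = NULL) {
  cnt <- .countMatrix(x)
  if (ncol(cnt) < 2) stop("TMM needs at least two samples")
  lib <- colSums(cnt)
  if (any(lib <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(cnt)[lib <= 0], collapse = ", "))
  if (is.null(refColumn)) {
    uq <- apply(cnt, 2, function(y) quantile(y / sum(y), 0.75))
    refColumn <- which.min(abs(uq - mean(uq)))
  }
  refC <- cnt[, refColumn]
  refL <- lib[refColumn]
  f <- vapply(seq_len(ncol(cnt)), function(j) {
    obsC <- cnt[, j]
    obsL <- lib[j]
    ok <- obsC > 0 & refC > 0
    if (!any(ok))
      stop("sample '", colnames(cnt)[j],
           "' shares no co-expressed genes with the reference")
    oc <- obsC[ok]; rc <- refC[ok]
    M <- log2((oc / obsL) / (rc / refL))
    A <- 0.5 * log2((oc / obsL) * (rc / refL))
    w <- (obsL - oc) / (obsL * oc) + (refL - rc) / (refL * rc)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    n <- length(M)
    if (!n) return(1)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep) || sum(1 / w[keep]) == 0) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(cnt)
  f
}

.pseudoCounts <- function(cnt, normFactors) {
  effLib <- colSums(cnt) * normFactors
  geo <- exp(mean(log(effLib)))
  list(pseudo = sweep(cnt, 2, geo / effLib, "*"), effLib = effLib,
       common = geo)
}

## Per-gene conditional NB log-likelihood given within-group sums, at a
## single dispersion value; constant-in-phi terms are dropped.
.condLogLik <- function(pseudo, groups, phi) {
  r <- 1 / max(phi, 1e-10)
  ll <- numeric(nrow(pseudo))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    n <- length(cols)
    if (n < 2) next
    y <- pseudo[, cols, drop = FALSE]
    S <- rowSums(y)
    ll <- ll + rowSums(lgamma(y + r)) - n * lgamma(r) -
      lgamma(S + n * r) + lgamma(n * r)
  }
  ll
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximises the conditional (residual-adjusted) NB
#' log-likelihood of counts given their within-group sums, after scaling
#' all libraries to a common effective size (mean scaling of TMM-adjusted
#' library sizes). Tagwise dispersions maximise a weighted combination of
#' each gene's own conditional likelihood and the average likelihood
#' across genes, shrinking genes with little information towards the
#' common value; the weight corresponds to `priorDf` prior degrees of
#' freedom.
#'
#' @param x a [CohortCountSet-class] (groups taken from its cohorts) or a
#'   count matrix with `groups` supplied.
#' @param groups group label per sample (defaults to `cohorts(x)`).
#' @param normFactors per-sample normalisation factors (default
#'   [tmmFactors()]).
#' @param priorDf prior degrees of freedom for tagwise shrinkage
#'   (default 10).
#' @param gridLength grid resolution for the tagwise maximisation.
#' @return list with elements `common` (scalar), `tagwise` (named per-gene
#'   vector) and `priorDf`.
#' @export
estimateNBDispersions <- function(x, groups = NULL, normFactors = NULL,
                                  priorDf = 10, gridLength = 33) {
  cnt <- .countMatrix(x)
  if (is.null(groups)) {
    if (!is(x, "CohortCountSet"))
      stop("supply 'groups' for a plain matrix")
    groups <- cohorts(x)
  }
  if (length(unique(groups)) < 2 && all(table(groups) < 2))
    stop("need at least one group with replicates")
  dfRes <- sum(pmax(table(groups) - 1, 0))
  if (dfRes == 0)
    stop("no replication in any group; supply a fixed dispersion instead")
  if (is.null(normFactors)) normFactors <- tmmFactors(cnt)
  pseudo <- .pseudoCounts(cnt, normFactors)$pseudo

  common <- exp(optimize(function(lphi)
    sum(.condLogLik(pseudo, groups, exp(lphi))),
    lower = log(1e-6), upper = log(20), maximum = TRUE, tol = 1e-6)$maximum)

  grid <- pmax(common, 1e-6) * 2^seq(-8, 8, length.out = gridLength)
  L <- vapply(grid, function(p) .condLogLik(pseudo, groups, p),
              numeric(nrow(pseudo)))
  lbar <- colMeans(L)
  priorN <- priorDf / dfRes
  score <- L + matrix(priorN * lbar, nrow(L), length(grid), byrow = TRUE)
  best <- max.col(score, ties.method = "first")
  ## quadratic refinement on the log2-dispersion grid
  step <- diff(log(grid))[1]
  tag <- vapply(seq_len(nrow(score)), function(i) {
    k <- best[i]
    if (k == 1 || k == length(grid)) return(grid[k])
    y1 <- score[i, k - 1]; y2 <- score[i, k]; y3 <- score[i, k + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den < 0) 0.5 * (y1 - y3) / den else 0
    exp(log(grid[k]) + max(-1, min(1, off)) * step)
  }, 0)
  names(tag) <- rownames(cnt)
  list(common = common, tagwise = pmax(tag, 0), priorDf = priorDf)
}

## Two-sided conditional exact p for one gene: doubling the smaller tail
## of the distribution of the group-B sum given the total.
.condExactP <- function(sA, sB, nA, nB, phi) {
  total <- sA + sB
  if (total == 0) return(1)
  mu0 <- total / (nA + nB)
  s <- 0:total
  lw <- if (phi <= 0)
    dpois(s, nB * mu0, log = TRUE) + dpois(total - s, nA * mu0, log = TRUE)
  else
    dnbinom(s, size = nB / phi, mu = nB * mu0, log = TRUE) +
      dnbinom(total - s, size = nA / phi, mu = nA * mu0, log = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  pLo <- sum(w[s <= sB])
  pHi <- sum(w[s >= sB])
  min(1, 2 * min(pLo, pHi))
}

#' Negative-binomial exact test for a two-group contrast
#'
#' Counts are scaled to a common effective library size (library size
#' times normalisation factor, mean scaling). Per gene, the two-sided
#' exact p-value is twice the smaller tail (capped at 1) of the
#' conditional distribution of the group-B pseudo-count sum given the
#' total, under NB sampling with the supplied dispersion; a zero
#' dispersion gives the Poisson limit, whose conditional distribution is
#' binomial. The log2 fold change of B over A is computed from mean
#' pseudo-counts with a small prior count added to each group mean.
#'
#' @param x a [CohortCountSet-class] or count matrix.
#' @param groupA,groupB cohort labels (for a `CohortCountSet`) or logical/
#'   integer column selectors.
#' @param dispersion per-gene dispersion vector, a scalar, or `NULL` to
#'   estimate tagwise dispersions from `x`.
#' @param normFactors per-sample factors (default [tmmFactors()] of the
#'   selected samples' full object).
#' @param priorCount prior count added to each group mean for the fold
#'   change (default 0.125).
#' @return data.frame with columns `gene`, `logFC` (B vs A), `PValue`,
#'   `FDR` (BH-adjusted), `meanCpmA`, `meanCpmB`.
#' @export
nbExactTest <- function(x, groupA, groupB, dispersion = NULL,
                        normFactors = NULL, priorCount = 0.125) {
  cnt <- .countMatrix(x)
  if (is(x, "CohortCountSet") && is.character(groupA)) {
    co <- cohorts(x)
    selA <- co %in% groupA
    selB <- co %in% groupB
  } else {
    selA <- groupA
    selB <- groupB
    if (!is.logical(selA)) selA <- seq_len(ncol(cnt)) %in% selA
    if (!is.logical(selB)) selB <- seq_len(ncol(cnt)) %in% selB
  }
  if (!any(selA) || !any(selB)) stop("both groups must be non-empty")
  if (is.null(normFactors)) normFactors <- tmmFactors(cnt)
  sel <- selA | selB
  ps <- .pseudoCounts(cnt[, sel, drop = FALSE], normFactors[sel])
  pseudo <- ps$pseudo
  inB <- selB[sel]
  nA <- sum(!inB); nB <- sum(inB)
  if (is.null(dispersion)) {
    grp <- ifelse(inB, "B", "A")
    dispersion <- estimateNBDispersions(cnt[, sel, drop = FALSE],
                                        groups = grp,
                                        normFactors = normFactors[sel]
                                        )$tagwise
  }
  phi <- rep_len(dispersion, nrow(cnt))
  sA <- round(rowSums(pseudo[, !inB, drop = FALSE]))
  sB <- round(rowSums(pseudo[, inB, drop = FALSE]))
  p <- vapply(seq_len(nrow(cnt)), function(i)
    .condExactP(sA[i], sB[i], nA, nB, phi[i]), 0)
  mA <- sA / nA; mB <- sB / nB
  logFC <- log2((mB + priorCount) / (mA + priorCount))
  cpm <- countsPerMillion(cnt[, sel, drop = FALSE])
  res <- data.frame(gene = rownames(cnt), logFC = logFC, PValue = p,
                    FDR = bhAdjust(p),
                    meanCpmA = rowMeans(cpm[, !inB, drop = FALSE]),
                    meanCpmB = rowMeans(cpm[, inB, drop = FALSE]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min over j >= i of (m / j) p_(j)`, clipped at 1, returned in
#' the original input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (!n) return(numeric())
  o <- order(p)
  sp <- p[o] * n / seq_len(n)
  adj <- pmin(1, rev(cummin(rev(sp))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Call differentially expressed genes from a test table
#'
#' Genes with `FDR < fdrCutoff` (strict, matching the "FDR < 0.05"
#' convention) and `|logFC| > lfcCutoff`. No fold-change cutoff is applied
#' by default because ageing-related expression changes tend to be
#' subtle.
#'
#' @param table data.frame from [nbExactTest()] (columns `gene`, `logFC`,
#'   `FDR`).
#' @param fdrCutoff strict FDR threshold (default 0.05).
#' @param lfcCutoff strict absolute log2-fold-change threshold (default 0).
#' @param contrast name for the resulting list.
#' @return A [SignedGeneList-class].
#' @export
callDE <- function(table, fdrCutoff = 0.05, lfcCutoff = 0,
                   contrast = "contrast") {
  keep <- table$FDR < fdrCutoff & abs(table$logFC) > lfcCutoff
  SignedGeneList(contrast, table$gene[keep], table$logFC[keep],
                 fdr = table$FDR[keep])
}

#' Run all cohort-versus-reference contrasts
#'
#' Applies the full engine once per non-reference cohort: expression
#' filter on the whole matrix, TMM factors and tagwise dispersions from
#' all samples, then the exact test of each cohort against the reference.
#'
#' @param x a [CohortCountSet-class].
#' @param design a [CohortDesign-class]; its reference cohort is the
#'   baseline of every contrast.
#' @param minCpm,minSamples expression-filter thresholds.
#' @param fdrCutoff FDR threshold for [callDE()].
#' @param priorDf tagwise shrinkage prior degrees of freedom.
#' @return list with elements `tables` (named list of test data.frames),
#'   `lists` (named list of [SignedGeneList-class], keyed by cohort),
#'   `filtered` (the filtered `CohortCountSet`), `normFactors` and
#'   `dispersion`.
#' @export
contrastsVsReference <- function(x, design = defaultCohortDesign(),
                                 minCpm = 1, minSamples = 3,
                                 fdrCutoff = 0.05, priorDf = 10) {
  ref <- referenceCohort(design)
  present <- intersect(cohortLabels(design), unique(cohorts(x)))
  if (!ref %in% present) stop("reference cohort absent from the data")
  xf <- filterByExpression(x, minCpm, minSamples)
  nf <- tmmFactors(xf)
  disp <- estimateNBDispersions(xf, normFactors = nf, priorDf = priorDf)
  others <- setdiff(present, ref)
  tables <- lapply(others, function(co)
    nbExactTest(xf, ref, co, dispersion = disp$tagwise, normFactors = nf))
  names(tables) <- others
  lists <- lapply(others, function(co)
    callDE(tables[[co]], fdrCutoff = fdrCutoff,
           contrast = paste0(co, "_vs_", ref)))
  names(lists) <- others
  list(tables = tables, lists = lists, filtered = xf, normFactors = nf,
       dispersion = disp)
}
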