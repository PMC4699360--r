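## Direction-aware set algebra over per-contrast DE lists. All operations
## are pure; gene order of a result follows the first input list.

.signsOf <- function(x) directions(x)

#' Direction-consistent intersection of signed gene lists
#'
#' Genes present in every list with an identical direction sign; log2
#' fold changes (and FDR values) are carried from the first list.
#'
#' @param ... two or more [SignedGeneList-class] objects, or a single
#'   list of them.
#' @param contrast name for the result (default derived from the inputs).
#' @return A [SignedGeneList-class].
#' @examples
#' a <- SignedGeneList("a", c("g1", "g2"), c(1, -2))
#' b <- SignedGeneList("b", c("g1", "g2"), c(2, 2))
#' geneIds(signedIntersect(a, b))  # g2 drops: opposite direction
#' @export
signedIntersect <- function(..., contrast = NULL) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) &&
      !is(lists[[1]], "SignedGeneList"))
    lists <- lists[[1]]
  if (length(lists) < 2L) stop("need at least two lists")
  first <- lists[[1]]
  keep <- rep(TRUE, length(first))
  s1 <- sign(first@log2FC)
  for (l in lists[-1]) {
    s <- .signsOf(l)
    m <- s[first@genes]
    keep <- keep & !is.na(m) & m == s1
  }
  if (is.null(contrast))
    contrast <- paste(vapply(lists, contrastName, ""), collapse = " & ")
  SignedGeneList(contrast, first@genes[keep], first@log2FC[keep],
                 fdr = first@fdr[keep])
}

#' Same-direction subtraction of signed gene lists
#'
#' Removes from `a` the genes that appear in `b` with the SAME direction;
#' a gene changing in the opposite direction in `b` does not remove it.
#' This is the "same trend" exclusion used to strip confounded genes from
#' a derived list.
#'
#' @param a,b [SignedGeneList-class] objects.
#' @param contrast name for the result (default `a`'s name).
#' @return A [SignedGeneList-class].
#' @export
signedSubtract <- function(a, b, contrast = contrastName(a)) {
  sb <- .signsOf(b)
  m <- sb[a@genes]
  drop <- !is.na(m) & m == sign(a@log2FC)
  SignedGeneList(contrast, a@genes[!drop], a@log2FC[!drop],
                 fdr = a@fdr[!drop])
}

#' Same-direction symmetric difference of two signed gene lists
#'
#' Genes in exactly one list, plus genes in both lists with opposite
#' directions: `signedSubtract(a, b)` followed by the genes of
#' `signedSubtract(b, a)` not already included.
#'
#' @param a,b [SignedGeneList-class] objects.
#' @param contrast name for the result.
#' @return A [SignedGeneList-class].
#' @export
signedSymmetricDiff <- function(a, b,
                                contrast = paste(contrastName(a), "xor",
                                                 contrastName(b))) {
  left <- signedSubtract(a, b)
  right <- signedSubtract(b, a)
  add <- !right@genes %in% left@genes
  SignedGeneList(contrast, c(left@genes, right@genes[add]),
                 c(left@log2FC, right@log2FC[add]),
                 fdr = c(left@fdr, right@fdr[add]))
}

#' Percentage overlap of two signed gene lists
#'
#' `100 * |signedIntersect(a, b)| / |basis|`, where the basis is either
#' the genes of `a` or the union of both gene sets (direction ignored in
#' the basis, respected in the numerator).
#'
#' @param a,b [SignedGeneList-class] objects.
#' @param basis `"a"` or `"union"`.
#' @return percentage in `[0, 100]`.
#' @export
overlapPercentage <- function(a, b, basis = c("a", "union")) {
  basis <- match.arg(basis)
  denom <- if (basis == "a") length(a)
           else length(union(a@genes, b@genes))
  if (denom == 0) stop("basis set is empty")
  100 * length(signedIntersect(a, b)) / denom
}

.getContrast <- function(contrasts, cohort, what = "procedure") {
  if (is.null(contrasts[[cohort]]))
    stop("missing required contrast for cohort '", cohort, "' (", what, ")")
  contrasts[[cohort]]
}

#' Shared diet expression profile across selected cohorts
#'
#' The direction-consistent intersection of the versus-reference DE lists
#' of the selected cohorts — the generalisation of the shared CR/LA
#' "neuroprotective profile".
#'
#' @param design a [CohortDesign-class].
#' @param contrasts named list of [SignedGeneList-class], keyed by cohort
#'   label (each versus the reference).
#' @param cohortSelector character vector of cohort labels (>= 2) or a
#'   predicate function over the design rows.
#' @return A [SignedGeneList-class].
#' @export
sharedDietProfile <- function(design, contrasts, cohortSelector) {
  if (is.function(cohortSelector)) {
    d <- design@design
    cohortSelector <- d$cohort[vapply(seq_len(nrow(d)), function(i)
      isTRUE(cohortSelector(d[i, ])), TRUE)]
  }
  cohortSelector <- setdiff(cohortSelector, referenceCohort(design))
  if (length(cohortSelector) < 2)
    stop("selector must match at least two non-reference cohorts")
  sel <- lapply(cohortSelector, .getContrast, contrasts = contrasts,
                what = "sharedDietProfile")
  signedIntersect(sel, contrast = paste0("shared(",
                                         paste(cohortSelector,
                                               collapse = ","), ")"))
}

#' Dietary-memory gene derivation
#'
#' Three-step comparison of the diet-switch cohort lists (all versus the
#' reference AL cohort):
#' \enumerate{
#'   \item `List1`: DE genes of the longevity-retaining switch cohort
#'     CR>AL+LA, minus genes with the same trend in the confounder
#'     cohorts AL+LA>CR or CR>AL (LA supplementation or switching without
#'     extended longevity).
#'   \item `List2`: DE genes of AL>CR (switch to CR, extended longevity)
#'     minus same-trend genes of AL+LA>CR — genes whose response to the
#'     switch LA disrupts.
#'   \item `List3`: the same-direction symmetric difference of AL+LA>CR
#'     and CR>AL+LA — the effect of supplementing LA before versus after
#'     the switch.
#' }
#' The final list combines genes appearing in at least two of the three
#' lists by default; each gene is tagged with its source lists.
#'
#' @param design a [CohortDesign-class].
#' @param contrasts named list of [SignedGeneList-class] keyed by cohort.
#' @param combine `"atLeast2"` (default), `"union"` or `"intersect"` —
#'   how the three lists are combined.
#' @param confounderOp `"subtract"` (default: same-trend exclusion) or
#'   `"intersect"` for steps 1 and 2.
#' @param memoryCohort,laBeforeCohort,switchCohort,plainSwitchCohort
#'   cohort labels of the four contrasts used (defaults follow the
#'   seven-cohort design).
#' @return A [SignedGeneList-class] with an `info` column `sources`.
#' @export
dietaryMemoryGenes <- function(design, contrasts,
                               combine = c("atLeast2", "union",
                                           "intersect"),
                               confounderOp = c("subtract", "intersect"),
                               memoryCohort = "CR>AL+LA",
                               laBeforeCohort = "AL+LA>CR",
                               switchCohort = "AL>CR",
                               plainSwitchCohort = "CR>AL") {
  combine <- match.arg(combine)
  confounderOp <- match.arg(confounderOp)
  mem <- .getContrast(contrasts, memoryCohort, "dietaryMemoryGenes")
  laB <- .getContrast(contrasts, laBeforeCohort, "dietaryMemoryGenes")
  sw <- .getContrast(contrasts, switchCohort, "dietaryMemoryGenes")
  pSw <- .getContrast(contrasts, plainSwitchCohort, "dietaryMemoryGenes")

  step <- function(a, b) {
    if (confounderOp == "subtract") signedSubtract(a, b)
    else signedIntersect(a, b)
  }
  list1 <- step(step(mem, laB), pSw)
  list2 <- step(sw, laB)
  list3 <- signedSymmetricDiff(laB, mem)

  lists <- list(list1 = list1, list2 = list2, list3 = list3)
  tally <- table(unlist(lapply(lists, geneIds)))
  need <- switch(combine, atLeast2 = 2L, union = 1L, intersect = 3L)
  keepGenes <- names(tally)[tally >= need]

  ## carry sign/FC from the first list containing each gene
  out <- data.frame(gene = character(), log2FC = numeric(),
                    fdr = numeric(), stringsAsFactors = FALSE)
  for (l in lists) {
    add <- l@genes %in% keepGenes & !l@genes %in% out$gene
    out <- rbind(out, data.frame(gene = l@genes[add],
                                 log2FC = l@log2FC[add],
                                 fdr = l@fdr[add],
                                 stringsAsFactors = FALSE))
  }
  src <- vapply(out$gene, function(g)
    paste(names(lists)[vapply(lists, function(l) g %in% l@genes, TRUE)],
          collapse = "+"), "")
  SignedGeneList("dietary_memory", out$gene, out$log2FC, fdr = out$fdr,
                 info = data.frame(sources = src,
                                   stringsAsFactors = FALSE))
}

#' Longevity gene derivation
#'
#' Genes DE with a consistent direction in every extended-longevity
#' cohort (versus the reference), with a same-trend exclusion against
#' every baseline LA-supplemented cohort — LA-driven changes without a
#' longevity benefit do not count as longevity genes.
#'
#' @param design a [CohortDesign-class] marking at least one extended and
#'   one baseline cohort.
#' @param contrasts named list of [SignedGeneList-class] keyed by cohort.
#' @param require `"all"` (default: DE in every extended cohort) or
#'   `"any"` (DE in at least one, direction-consistent where shared).
#' @return A [SignedGeneList-class]; the `info` slot carries the
#'   per-extended-cohort log2 fold changes.
#' @export
longevityGenes <- function(design, contrasts, require = c("all", "any")) {
  require <- match.arg(require)
  ext <- extendedCohorts(design)
  base <- baselineLaCohorts(design)
  if (!length(ext)) stop("design marks no extended-longevity cohort")
  extLists <- lapply(ext, .getContrast, contrasts = contrasts,
                     what = "longevityGenes")
  names(extLists) <- ext
  core <- if (require == "all" && length(extLists) > 1)
    signedIntersect(extLists, contrast = "longevity")
  else if (length(extLists) == 1) extLists[[1]]
  else {
    ## union with direction consistency: drop genes with conflicting signs
    allg <- unlist(lapply(extLists, geneIds))
    sgn <- unlist(lapply(extLists, function(l) sign(l@log2FC)))
    agg <- tapply(sgn, allg, function(s) if (length(unique(s)) == 1)
      unique(s) else 0)
    keep <- names(agg)[agg != 0]
    fc <- unlist(lapply(extLists, function(l)
      setNames(l@log2FC, l@genes)))
    SignedGeneList("longevity", keep, fc[keep])
  }
  for (co in base)
    core <- signedSubtract(core,
                           .getContrast(contrasts, co, "longevityGenes"),
                           contrast = "longevity")
  fcs <- do.call(cbind, lapply(extLists, function(l) {
    v <- setNames(l@log2FC, l@genes)
    unname(v[core@genes])
  }))
  if (length(core)) {
    fcs <- as.data.frame(fcs)
    colnames(fcs) <- paste0("log2FC_", gsub("[^A-Za-z0-9]+", ".", ext))
    core@info <- fcs
  }
  core
}
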