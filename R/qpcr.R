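#' Convert a percent amplification efficiency to an amplification factor
#'
#' A 100 % efficient assay doubles the product each cycle (`E = 2`);
#' `E = 1 + efficiency / 100`.
#'
#' @param percent efficiency in percent (e.g. 93 gives `E = 1.93`).
#' @return amplification factor.
#' @export
percentToEfficiency <- function(percent) 1 + percent / 100

.deltaCt <- function(assay) {
  ## arithmetic mean of reference Cts == geometric mean of reference
  ## quantities, the standard multi-reference combiner
  refMean <- mean(vapply(assay@referenceCts, mean, 0))
  mean(assay@targetCt) - refMean
}

#' Efficiency-corrected delta-delta-Ct expression ratio
#'
#' `dCt = mean(target Ct) - mean(reference panel Ct)` per group;
#' `ddCt = dCt(case) - dCt(control)`; the expression ratio of case over
#' control is `E^(-ddCt)` with the target assay's amplification factor
#' `E`. With `method = "perReplicate"` the per-group dCt is the mean of
#' replicate-wise dCt values (identical for balanced replicates).
#'
#' @param case,control [QpcrAssay-class] objects for the same target with
#'   a shared reference panel.
#' @param method `"mean"` (default) or `"perReplicate"`.
#' @return positive expression ratio (case / control).
#' @examples
#' a <- QpcrAssay("GRM1", c(24, 24.1), list(Hprt1 = c(20, 20)),
#'                efficiency = 2, group = "CR")
#' b <- QpcrAssay("GRM1", c(25, 25.1), list(Hprt1 = c(20, 20)),
#'                efficiency = 2, group = "AL")
#' deltaDeltaCt(a, b)  # about one cycle earlier in CR: ratio ~2
#' @export
deltaDeltaCt <- function(case, control, method = c("mean",
                                                   "perReplicate")) {
  method <- match.arg(method)
  if (!setequal(names(case@referenceCts), names(control@referenceCts)))
    stop("case and control must share the same reference panel")
  if (case@targetName != control@targetName)
    stop("case and control must assay the same target")
  dct <- function(a) {
    if (method == "mean") return(.deltaCt(a))
    refMat <- vapply(a@referenceCts, function(x)
      rep_len(x, length(a@targetCt)), numeric(length(a@targetCt)))
    mean(a@targetCt - rowMeans(as.matrix(refMat)))
  }
  ddct <- dct(case) - dct(control)
  case@efficiency^(-ddct)
}

#' Convert an expression ratio to a signed fold change
#'
#' Bar-chart convention for qPCR results: up-regulated samples
#' (`ratio >= 1`) report `ratio - 1`, down-regulated samples report
#' `(-1 / ratio) + 1`; the function is continuous at ratio 1 (value 0)
#' and antisymmetric under `ratio <-> 1/ratio`.
#'
#' @param ratio positive expression ratio(s).
#' @return signed fold change(s).
#' @examples
#' ratioToSignedFC(c(2, 1, 0.5))  # +1, 0, -1
#' @export
ratioToSignedFC <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be positive")
  ifelse(ratio >= 1, ratio - 1, (-1 / ratio) + 1)
}

#' Standard error of a log2 fold change
#'
#' `(se / |mean|) * log2(e)` — the delta-method standard error of
#' `log2(mean)` given the standard error of the mean on the linear scale.
#'
#' @param se standard error on the linear scale (>= 0).
#' @param mean the linear-scale mean (non-zero).
#' @return standard error on the log2 scale.
#' @export
log2fcStandardError <- function(se, mean) {
  if (any(mean == 0)) stop("mean must be non-zero")
  if (any(se < 0)) stop("se must be non-negative")
  (se / abs(mean)) * log2(exp(1))
}

#' Summarise a Ct table into qPCR fold changes
#'
#' Takes a long-format Ct table (columns `sample`, `gene`, `replicate`,
#' `Ct`, `role` = `"target"`/`"reference"`, `group`) plus per-target
#' amplification factors, and returns per-target ratio, signed fold
#' change, log2 fold change and its standard error for a case group
#' versus a control group.
#'
#' @param ct data.frame as described above.
#' @param caseGroup,controlGroup group labels.
#' @param efficiencies named numeric vector of amplification factors per
#'   target gene (default 2 for all).
#' @return data.frame with one row per target gene.
#' @export
qpcrFoldChanges <- function(ct, caseGroup, controlGroup,
                            efficiencies = NULL) {
  need <- c("sample", "gene", "Ct", "role", "group")
  if (!all(need %in% colnames(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  targets <- unique(ct$gene[ct$role == "target"])
  refs <- unique(ct$gene[ct$role == "reference"])
  if (!length(refs)) stop("no reference genes in the Ct table")
  mk <- function(gene, grp) {
    eff <- if (!is.null(efficiencies) && gene %in% names(efficiencies))
      efficiencies[[gene]] else 2
    QpcrAssay(gene,
              ct$Ct[ct$gene == gene & ct$group == grp],
              lapply(setNames(refs, refs), function(r)
                ct$Ct[ct$gene == r & ct$group == grp]),
              efficiency = eff, group = grp)
  }
  do.call(rbind, lapply(targets, function(g) {
    ratio <- deltaDeltaCt(mk(g, caseGroup), mk(g, controlGroup))
    caseCts <- ct$Ct[ct$gene == g & ct$group == caseGroup]
    se <- if (length(caseCts) > 1)
      stats::sd(caseCts) / sqrt(length(caseCts)) else 0
    data.frame(gene = g, ratio = ratio,
               signedFC = ratioToSignedFC(ratio), log2FC = log2(ratio),
               log2SE = log2fcStandardError(se, mean(caseCts)),
               stringsAsFactors = FALSE)
  }))
}
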