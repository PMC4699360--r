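## Readers and writers for the plain-text interchange formats: counts as
## TSV or MatrixMarket, sample sheets, signed gene lists, DE tables,
## PPI edge lists, LAG lists, ortholog tables and GMT collections.

#' Write a count container to disk
#'
#' TSV format: a `gene` id column plus one column per sample; the sample
#' sheet (`<prefix>_samples.tsv`) carries `sample_id` and `cohort`.
#' MatrixMarket format writes `<prefix>.mtx` with row/column name
#' sidecars.
#'
#' @param x a [CohortCountSet-class].
#' @param prefix output path prefix.
#' @param format `"tsv"` or `"mtx"`.
#' @return invisibly, the paths written.
#' @export
writeCounts <- function(x, prefix, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  cnt <- SummarizedExperiment::assay(x, "counts")
  paths <- character()
  if (format == "tsv") {
    f <- paste0(prefix, "_counts.tsv")
    write.table(data.frame(gene = rownames(cnt), cnt, check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- f
  } else {
    f <- paste0(prefix, ".mtx")
    Matrix::writeMM(Matrix::Matrix(cnt, sparse = TRUE), f)
    writeLines(rownames(cnt), paste0(prefix, "_rows.txt"))
    writeLines(colnames(cnt), paste0(prefix, "_cols.txt"))
    paths <- c(f, paste0(prefix, "_rows.txt"), paste0(prefix, "_cols.txt"))
  }
  sf <- paste0(prefix, "_samples.tsv")
  write.table(data.frame(sample_id = colnames(cnt), cohort = cohorts(x)),
              sf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, sf))
}

#' Read a count container from disk
#'
#' @param file counts TSV (gene column + samples) or MatrixMarket file.
#' @param samplesFile sample sheet TSV with columns `sample_id`,
#'   `cohort`.
#' @param format `"tsv"` or `"mtx"`; `"mtx"` expects `_rows.txt` /
#'   `_cols.txt` sidecars next to the matrix file.
#' @return A [CohortCountSet-class].
#' @export
readCounts <- function(file, samplesFile, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- read.delim(file, check.names = FALSE)
    cnt <- as.matrix(d[, -1, drop = FALSE])
    rownames(cnt) <- d[[1]]
  } else {
    cnt <- as.matrix(Matrix::readMM(file))
    prefix <- sub("\\.mtx$", "", file)
    rownames(cnt) <- readLines(paste0(prefix, "_rows.txt"))
    colnames(cnt) <- readLines(paste0(prefix, "_cols.txt"))
  }
  ss <- read.delim(samplesFile)
  if (!all(colnames(cnt) %in% ss$sample_id))
    stop("sample sheet does not cover all samples")
  CohortCountSet(cnt, cohort = ss$cohort[match(colnames(cnt),
                                               ss$sample_id)])
}

#' Write a signed gene list as TSV
#' @param x a [SignedGeneList-class].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeSignedGeneList <- function(x, file) {
  write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Read a signed gene list from TSV
#' @param file path to a TSV with columns `gene`, `log2FC`, `fdr`.
#' @param contrast contrast name (default: the file name).
#' @return A [SignedGeneList-class].
#' @export
readSignedGeneList <- function(file, contrast = basename(file)) {
  d <- read.delim(file)
  SignedGeneList(contrast, d$gene, d$log2FC, fdr = d$fdr)
}

#' Write a DE test table as TSV
#' @param table data.frame from [nbExactTest()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeDETable <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Long-format export of contrast fold changes for heatmap tools
#'
#' One row per (gene, contrast) with the log2 fold change and a
#' significance flag — the long-format counterpart of a signed-list
#' heatmap.
#'
#' @param tables named list of DE tables (from [contrastsVsReference()]).
#' @param fdrCutoff significance threshold for the flag.
#' @return data.frame with columns `gene`, `contrast`, `log2FC`,
#'   `significant`.
#' @export
heatmapLongFormat <- function(tables, fdrCutoff = 0.05) {
  do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    data.frame(gene = t$gene, contrast = nm, log2FC = t$logFC,
               significant = t$FDR < fdrCutoff,
               stringsAsFactors = FALSE)
  }))
}

#' Read a PPI edge list
#'
#' TSV with two id columns (`node_a`, `node_b`); self-loops are dropped
#' (count reported via a message) and duplicate edges collapsed
#' order-insensitively.
#'
#' @param file path to the edge-list TSV.
#' @return an undirected `igraph` graph.
#' @export
readPPI <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  loops <- d[[1]] == d[[2]]
  if (any(loops)) message("dropped ", sum(loops), " self-loop(s)")
  d <- d[!loops, , drop = FALSE]
  g <- igraph::graph_from_data_frame(d[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Read a LAG list (one gene id per line)
#' @param file path; blank lines and `#` comments are ignored.
#' @return character vector of gene ids.
#' @export
readLagList <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read an ortholog table
#' @param file TSV with columns source, target, score (header optional
#'   names respected if present).
#' @param speciesFrom,speciesTo species labels.
#' @return An [OrthologMap-class].
#' @export
readOrthologMap <- function(file, speciesFrom = "a", speciesTo = "b") {
  d <- read.delim(file, stringsAsFactors = FALSE)
  colnames(d)[1:3] <- c("source", "target", "score")
  OrthologMap(d[, 1:3], speciesFrom, speciesTo)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param file output path.
#' @param descriptions optional character vector of set descriptions.
#' @return invisibly, `file`.
#' @export
writeGmt <- function(sets, file, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, file)
  invisible(file)
}

#' Read gene sets from GMT format
#' @param file path to a GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(file) {
  lines <- strsplit(readLines(file), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[`, "", 1))
}
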