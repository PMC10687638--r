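## Plain-text readers and writers for the pipeline's external formats.

#' Read a count matrix and sample sheet into a HomeologExperiment
#'
#' The counts TSV has gene ids in the first column and one column per
#' sample; the sample sheet TSV has columns `sample`, `condition`
#' (control/cold) and `replicate`.
#'
#' @param countsFile path to the counts TSV.
#' @param sampleFile path to the sample sheet TSV.
#' @param lengthsFile optional path to a lengths TSV (gene, length_bp).
#' @return a [HomeologExperiment-class].
#' @export
readCountsTSV <- function(countsFile, sampleFile, lengthsFile = NULL) {
  d <- read.delim(countsFile, stringsAsFactors = FALSE, check.names = FALSE)
  cts <- as.matrix(d[, -1, drop = FALSE])
  rownames(cts) <- d[[1]]
  ss <- read.delim(sampleFile, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition", "replicate") %in% colnames(ss)))
    stop("sample sheet needs columns sample, condition, replicate")
  miss <- setdiff(colnames(cts), ss$sample)
  if (length(miss))
    stop("sample(s) missing from the sheet: ", paste(miss, collapse = ", "))
  ss <- ss[match(colnames(cts), ss$sample), ]
  lengths <- if (!is.null(lengthsFile)) readGeneLengths(lengthsFile)
  HomeologExperiment(cts, ss$condition, ss$replicate, lengths = lengths)
}

#' Read a triplet map TSV (anchor, copy1, copy2, copy3)
#'
#' @param file path to the TSV.
#' @return a [TripletMap-class].
#' @export
readTripletMap <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("anchor", "copy1", "copy2", "copy3")
  if (!all(need %in% colnames(d)))
    stop("triplet map TSV needs columns ", paste(need, collapse = ", "))
  TripletMap(d$anchor, as.matrix(d[, c("copy1", "copy2", "copy3")]))
}

#' Write a simulated dataset as plain-text files
#'
#' Writes counts.tsv (first column `gene`), samples.tsv (sample,
#' condition, replicate), triplets.tsv (anchor, copy1..3), lengths.tsv
#' (gene, length_bp) and truth.json into `dir`.
#'
#' @param sim list from [simulateTripletDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  he <- sim$experiment
  cts <- data.frame(gene = rownames(he), counts(he), check.names = FALSE)
  write.table(cts, file.path(dir, "counts.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample = colnames(he),
    condition = conditions(he),
    replicate = colData(he)$replicate)
  write.table(ss, file.path(dir, "samples.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  tm <- sim$tripletMap
  mem <- tripletMembers(tm)
  tt <- data.frame(anchor = anchors(tm), copy1 = mem[, 1],
    copy2 = mem[, 2], copy3 = mem[, 3])
  write.table(tt, file.path(dir, "triplets.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  lengths <- geneLengths(he)
  write.table(data.frame(gene = names(lengths), length_bp = lengths),
    file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(
    triplets = as.data.frame(tripletTruth(sim$truth)),
    genes = as.data.frame(geneTruth(sim$truth))),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Write an expression matrix with a unit header comment
#'
#' @param expr matrix from [computeFPKM()]/[computeTPM()].
#' @param file output TSV; the first line is a `#` comment recording the
#'   unit (from the matrix's `unit` attribute) and normalization note.
#' @param note free-text provenance note (e.g. "TMM-normalized").
#' @export
writeExpressionTSV <- function(expr, file, note = "") {
  unit <- attr(expr, "unit")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s%s", if (is.null(unit)) "unknown" else unit,
    if (nzchar(note)) paste0(" ", note) else ""), con)
  write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write DE results as TSV
#'
#' Columns: gene, meanControl, meanCold, log2FC, pvalue, qvalue, call.
#'
#' @param deResults output of [deTest()].
#' @param file output TSV path.
#' @export
writeDETable <- function(deResults, file) {
  write.table(as.data.frame(deResults), file, sep = "\t", quote = FALSE,
    row.names = FALSE)
}
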