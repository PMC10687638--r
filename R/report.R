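## Publication-style summary report and the end-to-end pipeline driver.

#' Percentage with half-up rounding
#'
#' 100 * numerator / denominator, rounded half-up to `decimals` (the
#' printing convention of the summary tables; base `round()` rounds half
#' to even, which would print 76.5 as 76).
#'
#' @param numerator,denominator counts; the denominator must be > 0.
#' @param decimals digits kept (default 0).
#' @return the rounded percentage.
#' @examples
#' percentage(6323, 8320)       # 76
#' percentage(969, 8320, 1)     # 11.6
#' @export
percentage <- function(numerator, denominator, decimals = 0) {
  if (denominator <= 0) stop("denominator must be > 0")
  x <- 100 * numerator / denominator
  floor(x * 10^decimals + 0.5) / 10^decimals
}

#' Assemble the publication-style summary report
#'
#' Collects every stage's output into one structured list: DE totals,
#' presence-category counts with percentages (integer for the
#' all-three-expressed category, one decimal elsewhere), dominance-class
#' counts, cold-response type counts with the diverged-response
#' percentage, the fraction of up-regulated genes inside triplets, and
#' per-module DE counts. Missing stages leave explicit `NULL` gaps with a
#' warning. All percentages are recomputed from the counts via
#' [percentage()].
#'
#' @param classification output of [classifyTriplets()] (or `NULL`).
#' @param types output of [classifyColdTypes()] (or `NULL`).
#' @param deResults output of [deTest()] (or `NULL`).
#' @param tripletMap a [TripletMap-class] (or `NULL`).
#' @param moduleSummary output of [moduleDESummary()] (or `NULL`).
#' @param params list of parameter values and seeds for provenance.
#' @return a nested list, JSON-serializable via [writeReport()].
#' @export
buildReport <- function(classification = NULL, types = NULL,
                        deResults = NULL, tripletMap = NULL,
                        moduleSummary = NULL, params = list()) {
  report <- list(params = params)
  gaps <- character()

  if (is.null(deResults)) {
    gaps <- c(gaps, "deResults")
    report$de <- NULL
  } else {
    report$de <- list(
      nGenes = nrow(deResults),
      nUp = sum(deResults$call == "up"),
      nDown = sum(deResults$call == "down"))
  }

  if (is.null(classification)) {
    gaps <- c(gaps, "classification")
  } else {
    ntrip <- nrow(classification)
    pres <- vapply(c("3", "2", "1", "0"), function(k)
      sum(classification$presence == as.integer(k)), integer(1))
    report$presence <- list(
      nTriplets = ntrip,
      counts = as.list(pres),
      percent = list(
        "3" = percentage(pres[["3"]], ntrip, 0),
        "2" = percentage(pres[["2"]], ntrip, 1),
        "1" = percentage(pres[["1"]], ntrip, 1),
        "0" = percentage(pres[["0"]], ntrip, 1)))
    cls <- vapply(c("class1", "class2", "class3", "unclassified"),
      function(k) sum(classification$class == k), integer(1))
    report$classes <- as.list(cls)
  }

  if (is.null(types)) {
    gaps <- c(gaps, "types")
  } else {
    report$coldTypes <- summarizeColdTypes(types)
  }

  if (!is.null(deResults) && !is.null(tripletMap)) {
    up <- coldInducedSet(deResults)
    inTriplets <- sum(up %in% as.vector(tripletMembers(tripletMap)))
    report$upRegulated <- list(
      nUp = length(up),
      nUpInTriplets = inTriplets,
      percentUpInTriplets = if (length(up))
        percentage(inTriplets, length(up), 1) else NA_real_)
  }

  if (is.null(moduleSummary)) {
    gaps <- c(gaps, "moduleSummary")
  } else {
    report$modules <- lapply(seq_len(nrow(moduleSummary)), function(i)
      list(module = moduleSummary$module[i],
        size = moduleSummary$size[i],
        nUp = moduleSummary$nUp[i],
        nDown = moduleSummary$nDown[i]))
  }

  if (length(gaps)) {
    warning("report has gaps: ", paste(gaps, collapse = ", "))
    report$gaps <- gaps
  }
  report
}

#' Write a report as JSON
#'
#' @param report list from [buildReport()].
#' @param path output file.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline on a simulated dataset
#'
#' simulate -> FPKM/TPM -> TMM -> common dispersion -> DE -> dominance
#' classification -> cold typing -> coexpression -> report, with one seed
#' (the config's). The coexpression stage can be switched off for designs
#' with too few samples to correlate.
#'
#' @param config a [SimulationConfig-class].
#' @param coexpression run the network stage (default TRUE when the
#'   design has at least 3 samples).
#' @param enrichmentTerms optional term map (gene, term) for an
#'   enrichment of the recovered class-1 genes.
#' @return list with every stage output plus `report`.
#' @export
runPipeline <- function(config, coexpression = NULL,
                        enrichmentTerms = NULL) {
  sim <- simulateTripletDataset(config)
  he <- sim$experiment
  tm <- sim$tripletMap
  nf <- tmmFactors(he)
  model <- estimateCommonDispersion(he, normFactors = nf)
  de <- deTest(he, model = model, normFactors = nf)
  cls <- classifyTriplets(tm, he)
  fpkm <- computeFPKM(he)
  types <- classifyColdTypes(tm, coldInducedSet(de), fpkm, conditions(he))
  if (is.null(coexpression)) coexpression <- ncol(he) >= 3
  net <- NULL; modSummary <- NULL
  if (coexpression) {
    tpm <- computeTPM(he)
    net <- tryCatch(
      buildCoexpressionNetwork(tpm, seed = config@seed),
      error = function(e) {
        warning("coexpression stage skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(net)) modSummary <- moduleDESummary(net, de)
  }
  enr <- NULL
  if (!is.null(enrichmentTerms)) {
    class1Genes <- with(as.data.frame(cls), c(copy1[class == "class1"],
      copy2[class == "class1"], copy3[class == "class1"]))
    enr <- hypergeomEnrich(class1Genes, enrichmentTerms, rownames(he))
  }
  report <- suppressWarnings(buildReport(
    classification = cls, types = types, deResults = de,
    tripletMap = tm, moduleSummary = modSummary,
    params = list(seed = config@seed,
      nTriplets = config@nTriplets, nSingletons = config@nSingletons,
      repsPerCondition = config@repsPerCondition,
      baselineMean = config@baselineMean,
      dispersion = config@dispersion,
      dominanceFC = config@dominanceFC,
      inductionLFC = config@inductionLFC,
      phiHat = dispersion(model))))
  list(sim = sim, normFactors = nf, model = model, de = de,
    classification = cls, types = types, network = net,
    moduleSummary = modSummary, enrichment = enr, report = report)
}
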