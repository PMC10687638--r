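test_that("config validation names the offending field", {
  expect_error(SimulationConfig(classProportions = c(
    class1 = 0.5, class2 = 0.5, class3 = 0.2, unstructured = 0)),
    "classProportions")
  expect_error(SimulationConfig(dominanceFC = 1.5), "dominanceFC")
  expect_error(SimulationConfig(inductionLFC = 0.5), "inductionLFC")
  expect_error(SimulationConfig(nTriplets = -1), "nTriplets")
})

test_that("triplet-free config yields singleton-only dataset", {
  sim <- simulateTripletDataset(
    SimulationConfig(nTriplets = 0, nSingletons = 5, seed = 1))
  expect_equal(nrow(sim$experiment), 5L)
  expect_equal(length(sim$tripletMap), 0L)
  expect_equal(nrow(tripletTruth(sim$truth)), 0L)
})

test_that("same seed gives bit-identical output, different seed differs", {
  cfg <- SimulationConfig(nTriplets = 50, nSingletons = 20, seed = 7)
  s1 <- simulateTripletDataset(cfg)
  s2 <- simulateTripletDataset(cfg)
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(geneTruth(s1$truth)$trueLFC, geneTruth(s2$truth)$trueLFC)
  s3 <- simulateTripletDataset(
    SimulationConfig(nTriplets = 50, nSingletons = 20, seed = 8))
  expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("phi = 0 counts are Poisson: Pearson residuals have unit scale", {
  cfg <- SimulationConfig(nTriplets = 400, nSingletons = 0,
    baselineMean = 50, dispersion = 0, seed = 13)
  sim <- simulateTripletDataset(cfg)
  gt <- geneTruth(sim$truth)
  f <- S4Vectors::metadata(sim$experiment)$libFactor
  cold <- conditions(sim$experiment) == "cold"
  mu <- outer(gt$controlMean, f)
  mu[, cold] <- mu[, cold] * 2^gt$trueLFC
  cts <- counts(sim$experiment)
  ok <- mu > 0
  ratio <- mean((cts[ok] - mu[ok])^2 / mu[ok])  # E[(X-mu)^2]/mu = 1 for Poisson
  expect_gt(sum(ok), 1000)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("planted truth is consistent with the planted means", {
  cfg <- SimulationConfig(nTriplets = 300, nSingletons = 0, seed = 21)
  sim <- simulateTripletDataset(cfg)
  tt <- tripletTruth(sim$truth)
  gt <- geneTruth(sim$truth)
  ab <- matrix(gt$abundance[!is.na(gt$anchor)], ncol = 3, byrow = TRUE)
  for (k in which(tt$class == "class1" & tt$presence == 3L)) {
    a <- sort(ab[k, ], decreasing = TRUE)
    expect_gte(a[1] / a[2], cfg@dominanceFC)
    expect_gte(a[1] / a[3], cfg@dominanceFC)
  }
  for (k in which(tt$class == "class3" & tt$presence == 3L))
    expect_true(all(ab[k, ] == ab[k, 1]))
  # divergent Type 1 triplets have true inducibility ratio >= 2, similar < 2
  expect_true(all(tt$trueInducibilityRatio[tt$divergent == "divergent"] >= 2))
  expect_true(all(tt$trueInducibilityRatio[tt$divergent == "similar"] < 2))
  # unexpressed copies have zero counts everywhere
  zero <- gt$gene[!gt$expressed]
  expect_true(all(counts(sim$experiment)[zero, ] == 0))
  # presence category equals the number of expressed copies
  expr3 <- matrix(gt$expressed[!is.na(gt$anchor)], ncol = 3, byrow = TRUE)
  expect_equal(rowSums(expr3), as.numeric(tt$presence))
})

test_that("term map plants one enriched term and is deterministic", {
  sim <- simulateTripletDataset(
    SimulationConfig(nTriplets = 200, nSingletons = 50, seed = 3))
  tmap <- makeTermMap(sim$truth, enrichedTermSize = 15,
    backgroundTerms = 0, seed = 5)
  expect_equal(nrow(tmap), 15L)
  expect_equal(unique(tmap$term), "TERM_planted")
  tmap2 <- makeTermMap(sim$truth, 15, 0, seed = 5)
  expect_identical(as.data.frame(tmap), as.data.frame(tmap2))
  expect_error(makeTermMap(sim$truth, 1e6, 0), "exceeds")
})

test_that("planted term is recovered by enrichment ahead of background", {
  sim <- simulateTripletDataset(
    SimulationConfig(nTriplets = 300, nSingletons = 100, seed = 17))
  tt <- tripletTruth(sim$truth)
  gt <- geneTruth(sim$truth)
  tmap <- makeTermMap(sim$truth, enrichedTermSize = 20,
    backgroundTerms = 30, seed = 2)
  class1Genes <- gt$gene[!is.na(gt$anchor) &
    gt$anchor %in% tt$anchor[tt$class == "class1" & tt$presence == 3L]]
  res <- suppressMessages(
    hypergeomEnrich(class1Genes, tmap, gt$gene))
  expect_equal(res$term[1], "TERM_planted")
  bg <- res$p[res$term != "TERM_planted"]
  expect_lt(res$p[res$term == "TERM_planted"], median(bg))
})
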