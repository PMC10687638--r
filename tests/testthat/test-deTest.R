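test_that("exact test matches closed-form binomial at phi = 0", {
  # counts 10 vs 0, one replicate each: Binomial(10, 1/2) two-sided
  expect_equal(nbExactTest(10, 0, phi = 0), 2 / 1024, tolerance = 1e-12)
  # equal pseudo-counts in both groups: observed split is the mode
  expect_equal(nbExactTest(c(5, 5), c(5, 5), phi = 0.4), 1)
  expect_equal(nbExactTest(0, 0, phi = 0.1), 1)  # T = 0
  # phi = 0 equals the binomial (Poisson conditional) test, T <= 200
  for (tot in c(1, 2, 7, 50, 133, 200)) {
    sA <- tot %/% 3
    p <- nbExactTest(sA, tot - sA, phi = 0)
    pb <- stats::binom.test(sA, tot, 0.5)$p.value
    expect_equal(p, pb, tolerance = 1e-9)
  }
})

test_that("exact test equals brute-force enumeration across phi and T", {
  set.seed(101)
  for (phi in c(0, 0.1, 0.5)) {
    for (rep in 1:25) {
      tot <- sample(0:500, 1)
      sA <- if (tot > 0) sample(0:tot, 1) else 0
      nA <- sample(1:3, 1); nB <- sample(1:3, 1)
      yA <- c(sA, rep(0, nA - 1)); yB <- c(tot - sA, rep(0, nB - 1))
      expect_equal(nbExactTest(yA, yB, phi),
        bruteForceExactP(yA, yB, phi), tolerance = 1e-10)
    }
  }
})

test_that("p never increases as the split moves away from the mode", {
  for (phi in c(0, 0.3)) {
    tot <- 60
    p <- vapply(30:60, function(sA)
      nbExactTest(c(sA), c(tot - sA), phi), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("common dispersion: zero for identical replicates, recovered at 0.4", {
  m <- makeNBCounts(200, 4, mu = 50, phi = 0, seed = 6)
  m[, 2] <- m[, 1]; m[, 4] <- m[, 3]
  fit <- estimateCommonDispersion(m, groups = c("A", "A", "B", "B"))
  expect_equal(dispersion(fit), 0)

  y <- makeNBCounts(2000, 4, mu = 100, phi = 0.4, seed = 5)
  fit2 <- estimateCommonDispersion(y, groups = c("A", "A", "B", "B"))
  expect_lt(abs(dispersion(fit2) - 0.4) / 0.4, 0.25)
  # invariant to gene order permutation
  set.seed(7); perm <- sample(nrow(y))
  fit3 <- estimateCommonDispersion(y[perm, ],
    groups = c("A", "A", "B", "B"))
  expect_equal(dispersion(fit3), dispersion(fit2), tolerance = 1e-6)
  # degenerate input
  z <- matrix(0L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(fit4 <- estimateCommonDispersion(z, rep(c("A", "B"), 2)),
    "zero")
  expect_equal(dispersion(fit4), 0)
})

test_that("dispersion estimate agrees with edgeR's CML estimate", {
  skip_if_not_installed("edgeR")
  y <- makeNBCounts(1500, 4, mu = 80, phi = 0.25, seed = 8)
  ours <- dispersion(estimateCommonDispersion(y,
    groups = c("A", "A", "B", "B")))
  d <- edgeR::estimateCommonDisp(edgeR::DGEList(y,
    group = c("A", "A", "B", "B")))
  expect_lt(abs(ours - d$common.dispersion) / d$common.dispersion, 0.15)
})

test_that("DE calls apply strict printed thresholds", {
  res <- data.frame(
    log2FC = c(1.2, 1.0, -3, 2, -1.5),
    pvalue = c(0.005, 0.001, 0.02, 0.5, 0.009))
  out <- callDE(res)
  expect_equal(out$call, c("up", "ns", "ns", "ns", "down"))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2); p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
})

test_that("deTest recovers planted induction on an easy dataset", {
  sim <- simulateTripletDataset(SimulationConfig(
    nTriplets = 150, nSingletons = 50, dispersion = 0.02,
    inductionLFC = 3, seed = 12))
  de <- deTest(sim$experiment)
  gt <- geneTruth(sim$truth)
  induced <- gt$gene[gt$induced]
  quiet <- gt$gene[!gt$induced & gt$expressed]
  expect_gt(mean(de[induced, "call"] == "up"), 0.95)
  expect_lt(mean(de[quiet, "call"] == "up"), 0.02)
  # p-values live in (0, 1]
  expect_true(all(de$pvalue > 0 & de$pvalue <= 1))
  # up calls respect the thresholds
  up <- de$call == "up"
  expect_true(all(de$log2FC[up] > 1 & de$pvalue[up] < 0.01))
})

test_that("type-I error is near nominal under the null", {
  set.seed(42)
  n <- 1500
  y <- matrix(rnbinom(n * 4, mu = 100, size = 1 / 0.4), n)
  pv <- vapply(seq_len(n), function(i)
    nbExactTest(y[i, 1:2], y[i, 3:4], 0.4), numeric(1))
  expect_gt(mean(pv < 0.05), 0.03)
  expect_lt(mean(pv < 0.05), 0.07)
})
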