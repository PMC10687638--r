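test_that("presence category counts copies above the threshold", {
  expect_equal(presenceCategory(c(5, 3, 0)), 2)
  expect_equal(presenceCategory(c(0, 0, 0)), 0)
  expect_equal(presenceCategory(c(0.4, 0.4, 0.4), 0.5), 0)
  expect_equal(presenceCategory(c(0.4, 0.4, 0.4), 0), 3)
})

test_that("classification rules follow the printed thresholds", {
  # one dominant copy
  expect_equal(classifyTriplet(c(a = 20, b = 5, c = 4),
    pairP = c(0.001, 0.001, 0.4), pairFC = c(4, 5, 1.25)), "class1")
  # all similar: FCs 1.11, 1.25, 1.13 all < 1.5
  expect_equal(classifyTriplet(c(a = 20, b = 18, c = 16),
    pairP = c(0.8, 0.5, 0.7), pairFC = c(20 / 18, 20 / 16, 18 / 16)),
    "class3")
  # top/mid FC 1.67 blocks class 1, but both high copies each beat the
  # third (p < 0.01, FC > 2), which is the printed class 2 rule
  expect_equal(classifyTriplet(c(a = 20, b = 12, c = 4),
    pairP = c(0.001, 0.001, 0.001), pairFC = c(20 / 12, 5, 3)),
    "class2")
  # same means but mid-vs-low not significant: no rule holds
  expect_equal(classifyTriplet(c(a = 20, b = 12, c = 4),
    pairP = c(0.001, 0.001, 0.2), pairFC = c(20 / 12, 5, 3)),
    "unclassified")
  # two dominant copies
  expect_equal(classifyTriplet(c(a = 20, b = 19, c = 4),
    pairP = c(0.9, 0.001, 0.001), pairFC = c(20 / 19, 5, 19 / 4)),
    "class2")
  # class guards: class3 needs all three copies expressed
  expect_equal(classifyTriplet(c(a = 0, b = 0, c = 0),
    pairP = c(1, 1, 1), pairFC = c(1, 1, 1)), "unclassified")
  # significant but sub-threshold FC stays unclassified
  expect_equal(classifyTriplet(c(a = 20, b = 11, c = 10),
    pairP = c(0.001, 0.001, 0.9), pairFC = c(1.82, 2, 1.1)),
    "unclassified")
})

test_that("pairwise tests are symmetric and length-aware", {
  pseudo <- rbind(g1 = c(100, 100), g2 = c(100, 100), g3 = c(0, 0))
  # equal counts, equal lengths: p = 1, FC = 1
  pw <- pairwiseHomeologTests(pseudo, fpkmMeans = c(1, 1, 0),
    lengths = c(1000, 1000, 1000), phi = 0.1)
  expect_equal(pw$p[1], 1)
  expect_equal(pw$fc[1], 1)
  # both copies zero: p = 1, FC = 1
  pw0 <- pairwiseHomeologTests(rbind(c(0, 0), c(0, 0), c(0, 0)),
    c(0, 0, 0), c(1000, 1000, 1000), phi = 0.1)
  expect_equal(pw0$p, rep(1, 3))
  expect_equal(pw0$fc, rep(1, 3))
  # equal counts but lengths 1000 vs 2000: FPKM FC is 2 while the test
  # compares per-kilobase rates (100 vs 50 per sample)
  pseudo2 <- rbind(g1 = c(100, 100), g2 = c(100, 100), g3 = c(100, 100))
  pw2 <- pairwiseHomeologTests(pseudo2, fpkmMeans = c(2, 1, 1),
    lengths = c(1000, 2000, 2000), phi = 0)
  expect_equal(pw2$fc[1], 2)
  expect_equal(pw2$p[1],
    bruteForceExactP(c(100, 100), c(50, 50), 0), tolerance = 1e-10)
  # symmetry under swapping the two copies
  pseudoS <- rbind(g1 = c(120, 90), g2 = c(40, 55), g3 = c(10, 20))
  pwA <- pairwiseHomeologTests(pseudoS, c(3, 1.5, 0.4),
    c(800, 900, 700), phi = 0.2)
  pwB <- pairwiseHomeologTests(pseudoS[c(2, 1, 3), ], c(1.5, 3, 0.4),
    c(900, 800, 700), phi = 0.2)
  expect_equal(pwA$p[1], pwB$p[1])
})

test_that("classification is invariant to member order and classes exclusive", {
  sim <- simulateTripletDataset(SimulationConfig(
    nTriplets = 60, nSingletons = 0, dispersion = 0.05, seed = 31))
  tm <- sim$tripletMap
  cls <- classifyTriplets(tm, sim$experiment)
  # permute the member columns of every triplet
  mem <- tripletMembers(tm)
  tmPerm <- TripletMap(anchors(tm), mem[, c(3, 1, 2)])
  clsPerm <- classifyTriplets(tmPerm, sim$experiment)
  expect_equal(cls$class, clsPerm$class)
  expect_equal(cls$presence, clsPerm$presence)
  expect_true(all(cls$class %in%
    c("class1", "class2", "class3", "unclassified")))
})

test_that("planted dominance classes are recovered under low noise", {
  sim <- simulateTripletDataset(SimulationConfig(
    nTriplets = 250, nSingletons = 0, dispersion = 0.01,
    baselineMean = 300, dominanceFC = 6, seed = 19))
  cls <- classifyTriplets(sim$tripletMap, sim$experiment)
  tt <- tripletTruth(sim$truth)
  expect_equal(cls$presence, as.integer(tt$presence))
  for (k in c("class1", "class2")) {
    planted <- tt$class == k
    expect_gt(mean(cls$class[planted] == k), 0.9)
  }
  # unclassified is a legal recovered outcome: counts need not cover all
  expect_true(sum(cls$class != "unclassified") <= nrow(cls))
})

test_that("missing triplet members raise a clear error", {
  sim <- simulateTripletDataset(SimulationConfig(
    nTriplets = 5, nSingletons = 0, seed = 2))
  tmBad <- TripletMap("X1", cbind("nope1", "nope2", "nope3"))
  expect_error(classifyTriplets(tmBad, sim$experiment), "absent")
})
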