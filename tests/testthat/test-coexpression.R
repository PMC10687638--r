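test_that("variable-gene filter keeps the top-variance expressed genes", {
  set.seed(3)
  tpm <- matrix(runif(40, 2, 100), 10, 4,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sel <- filterVariableGenes(tpm, topFraction = 0.2)
  expect_length(sel, 2)
  v <- apply(log2(tpm + 1), 1, var)
  expect_setequal(sel, names(sort(v, decreasing = TRUE))[1:2])
  # constant gene never selected while positive-variance genes remain
  tpm2 <- rbind(flat = rep(50, 4), tpm[1:2, ])
  sel2 <- filterVariableGenes(tpm2, topFraction = 2 / 3)
  expect_false("flat" %in% sel2)
  # everything at or below the TPM floor is an error
  expect_error(filterVariableGenes(matrix(0.5, 3, 4,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))), "TPM")
})

test_that("correlation edges are signed, thresholded and symmetric", {
  base <- c(1, 5, 20, 60)
  tpm <- rbind(a = base, b = 2 * base, c = rev(base),
    d = c(1, 2, 3, 5))
  colnames(tpm) <- paste0("s", 1:4)
  ed <- correlationEdges(tpm, rThreshold = 0.7)
  pairs <- paste(ed$geneA, ed$geneB)
  expect_true("a b" %in% pairs)     # r = 1
  expect_false(any(grepl("c", pairs) & grepl("a|b", pairs)))  # r < 0
  expect_true(all(ed$r > 0.7))
  expect_true(all(ed$geneA != ed$geneB))
  # hand-computed Pearson on 4 points: (1,2,3,4) vs (1,2,3,5) -> 0.943
  x <- rbind(p = c(1, 2, 3, 4), q = c(1, 2, 3, 5))
  colnames(x) <- paste0("s", 1:4)
  r <- cor(log2(x["p", ] + 1), log2(x["q", ] + 1))
  ed2 <- correlationEdges(x, rThreshold = 0.7)
  expect_equal(ed2$r, r)
  expect_gt(r, 0.7)
  # zero-variance genes are excluded with a warning
  expect_warning(correlationEdges(rbind(tpm, z = rep(7, 4))), "zero-variance")
  expect_error(correlationEdges(tpm[, 1:2]), ">= 3")
})

test_that("Leiden modules: disconnected cliques split, single edge holds", {
  cl5 <- t(combn(paste0("a", 1:5), 2))
  cl5b <- t(combn(paste0("b", 1:5), 2))
  edges <- data.frame(geneA = c(cl5[, 1], cl5b[, 1]),
    geneB = c(cl5[, 2], cl5b[, 2]), r = 0.9)
  mods <- detectModules(edges, seed = 1)
  expect_equal(length(unique(mods)), 2)
  expect_equal(length(unique(mods[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(mods[paste0("b", 1:5)])), 1)
  # a single edge makes one module of two at the default resolution
  one <- detectModules(data.frame(geneA = "x", geneB = "y", r = 0.8),
    seed = 1)
  expect_equal(unname(one), c(1L, 1L))
  # determinism and singleton handling
  m1 <- detectModules(edges, genes = c(unique(c(edges$geneA, edges$geneB)),
    "lonely"), seed = 9)
  m2 <- detectModules(edges, genes = c(unique(c(edges$geneA, edges$geneB)),
    "lonely"), seed = 9)
  expect_identical(m1, m2)
  expect_equal(sum(m1 == m1[["lonely"]]), 1)
})

test_that("planted coexpression blocks land in distinct modules", {
  tpm <- simulateCoexpressionBlocks(nBlocks = 2, genesPerBlock = 50,
    nSamples = 10, seed = 4)
  net <- buildCoexpressionNetwork(tpm, topFraction = 1, seed = 4)
  mods <- modules(net)
  expect_equal(length(unique(mods)), 2)
  bl <- attr(tpm, "block")[names(mods)]
  expect_equal(length(unique(mods[bl == 1])), 1)
  expect_equal(length(unique(mods[bl == 2])), 1)
  expect_true(all(networkEdges(net)$r > 0.7))
  # partition covers exactly the filtered node set
  expect_setequal(names(mods), rownames(tpm))
  # same seed, identical partition
  net2 <- buildCoexpressionNetwork(tpm, topFraction = 1, seed = 4)
  expect_identical(modules(net2), mods)
})

test_that("module DE summary counts up/down per module", {
  mods <- structure(c(1L, 1L, 1L, 2L, 2L),
    names = c("g1", "g2", "g3", "g4", "g5"))
  de <- callDE(S4Vectors::DataFrame(
    gene = c("g1", "g2", "g4", "g5"),
    log2FC = c(2, -2, 3, 0.2), pvalue = c(1e-4, 1e-4, 1e-4, 0.9)))
  expect_message(s <- moduleDESummary(mods, de), "absent")
  expect_equal(s$size, c(3L, 2L))
  expect_equal(s$nUp, c(1L, 1L))
  expect_equal(s$nDown, c(1L, 0L))
  empty <- moduleDESummary(structure(integer(), names = character()), de)
  expect_equal(nrow(empty), 0)
})
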