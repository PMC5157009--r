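# small helper: a hand-built map with given boundaries/weights
makeMap <- function(keys, weights, levels, sims, kInitial = 4L) {
  ontonet:::.mapFromLevels(keys, weights, sims, levels, kInitial,
    ontonet:::.discordanceVec(levels, sims))
}

test_that("design matrix has one entry per network level per pair", {
  training <- makeTraining(paste0("a", 1:3), paste0("b", 1:3),
    c(0.2, 0.5, 0.8))
  keys <- ontonet:::.pairKey(paste0("a", 1:3), paste0("b", 1:3))
  net1 <- makeNetwork(paste0("a", 1:3), paste0("b", 1:3), c(0.1, 0.5, 0.9),
    name = "n1")
  map1 <- makeMap(keys, c(0.1, 0.5, 0.9), c(1L, 1L, 2L), c(0.2, 0.5, 0.8))
  # network 2 misses pair 2 and has 3 levels
  net2 <- makeNetwork(c("a1", "a3", "x"), c("b1", "b3", "y"),
    c(0.2, 0.8, 0.5), genes = c(sort(c(paste0("a", 1:3),
      paste0("b", 1:3))), "x", "y"), name = "n2")
  map2 <- makeMap(keys[c(1, 3)], c(0.2, 0.8), c(1L, 2L), c(0.2, 0.8))

  dm <- buildDesignMatrix(list(net1, net2), list(map1, map2), training)
  M <- designMatrix(dm)
  expect_equal(dim(M), c(3L, 4L))        # N additivity: 2 + 2 columns
  cols <- designColumns(dm)
  for (net in unique(cols$network))
    expect_true(all(rowSums(M[, cols$network == net, drop = FALSE] != 0)
      <= 1))
  # pair 2 missing from network 2 -> zeros in its columns
  expect_true(all(M[2, cols$network == "n2"] == 0))
  # entries are the discretized level weights
  expect_equal(sort(unique(M[M != 0])),
    sort(unique(c(levelWeights(map1), levelWeights(map2)))))
})

test_that("a pair with no edge anywhere yields a warned zero row", {
  training <- makeTraining(paste0("a", 1:3), paste0("b", 1:3),
    c(0.2, 0.5, 0.8))
  keys <- ontonet:::.pairKey(paste0("a", 1:2), paste0("b", 1:2))
  net <- makeNetwork(paste0("a", 1:2), paste0("b", 1:2), c(0.1, 0.9),
    genes = sort(c(paste0("a", 1:3), paste0("b", 1:3))))
  map <- makeMap(keys, c(0.1, 0.9), c(1L, 2L), c(0.2, 0.5))
  expect_warning(dm <- buildDesignMatrix(list(net), list(map), training),
    "no edge")
  expect_true(all(designMatrix(dm)[3, ] == 0))
})

test_that("integration fit equals the closed-form CCA maximizer", {
  set.seed(5)
  M <- matrix(rnorm(30 * 6), 30, 6)
  s <- rnorm(30)
  cf <- fitIntegration(M, s)
  a <- integrationCoefficients(cf)
  expect_equal(sqrt(sum(a^2)), 1, tolerance = 1e-10)

  # oracle 1: correlation of the OLS fit of s on centered columns
  fit <- lm(s ~ M)
  expect_equal(achievedPcc(cf), cor(fitted(fit), s), tolerance = 1e-8)

  # oracle 2: beats 1000 random unit vectors
  best <- max(vapply(seq_len(1000), function(i) {
    b <- rnorm(6); b <- b / sqrt(sum(b^2))
    abs(cor(M %*% b, s))
  }, numeric(1)))
  expect_gte(achievedPcc(cf) + 1e-12, best)

  # single column: |PCC| with sign normalization
  cf1 <- fitIntegration(M[, 1, drop = FALSE], s)
  expect_equal(achievedPcc(cf1), abs(cor(M[, 1], s)), tolerance = 1e-10)
  expect_equal(abs(integrationCoefficients(cf1)), 1)

  # exact linear combination -> PCC 1
  sExact <- as.numeric(M %*% c(1, -2, 0, 0, 0.5, 0)) + 3
  expect_equal(achievedPcc(fitIntegration(M, sExact)), 1,
    tolerance = 1e-8)
})

test_that("achieved PCC is invariant to column scaling and s shifts", {
  set.seed(6)
  M <- matrix(rnorm(40 * 4), 40, 4)
  s <- rnorm(40)
  base <- achievedPcc(fitIntegration(M, s))
  M2 <- M %*% diag(c(10, 0.1, 3, 1))
  expect_equal(achievedPcc(fitIntegration(M2, s)), base,
    tolerance = 1e-8)
  expect_equal(achievedPcc(fitIntegration(M, s + 5)), base,
    tolerance = 1e-8)
})

test_that("degenerate fits are rejected", {
  M <- matrix(rnorm(20), 10, 2)
  expect_error(fitIntegration(M, rep(1, 10)), "constant")
  expect_error(fitIntegration(matrix(0, 10, 2), rnorm(10)), "zero")
})

test_that("the fit is at least as good as equal-weight summation", {
  set.seed(7)
  for (i in 1:5) {
    M <- matrix(abs(rnorm(25 * 5)), 25, 5)
    s <- as.numeric(M %*% runif(5)) + rnorm(25, 0, 0.5)
    cf <- fitIntegration(M, s)
    equal <- abs(cor(rowSums(M), s))
    expect_gte(achievedPcc(cf) + 1e-9, equal)
  }
})

test_that("network integration matches the direct summation oracle", {
  training <- makeTraining(paste0("a", 1:3), paste0("b", 1:3),
    c(0.2, 0.5, 0.8))
  keys <- ontonet:::.pairKey(paste0("a", 1:3), paste0("b", 1:3))
  net1 <- makeNetwork(paste0("a", 1:3), paste0("b", 1:3), c(0.1, 0.5, 0.9),
    name = "n1")
  map1 <- makeMap(keys, c(0.1, 0.5, 0.9), c(1L, 2L, 3L), c(0.2, 0.5, 0.8))
  net2 <- makeNetwork(c("a1", "a2"), c("b1", "b2"), c(0.3, 0.7),
    genes = sort(c(paste0("a", 1:3), paste0("b", 1:3))), name = "n2")
  map2 <- makeMap(keys[1:2], c(0.3, 0.7), c(1L, 2L), c(0.2, 0.5))
  dm <- buildDesignMatrix(list(net1, net2), list(map1, map2), training)
  cf <- fitIntegration(dm, trainingPairs(training)$similarity)

  integ <- integrateNetworks(list(net1, net2), list(map1, map2), cf,
    rescale = FALSE)
  e <- networkEdges(integ)
  key <- ontonet:::.pairKey(e$geneA, e$geneB)
  a <- integrationCoefficients(cf)
  lw1 <- levelWeights(map1); lw2 <- levelWeights(map2)
  # hand-computed sum of a_l * discretized weight per network
  expected1 <- a[1] * lw1[1] + a[4] * lw2[1]
  expect_equal(e$weight[key == keys[1]], unname(expected1))
  # pair 3 present in network 1 only
  expect_equal(e$weight[key == keys[3]], unname(a[3] * lw1[3]))
  # training-edge weights correlate with s at exactly the achieved PCC
  s <- trainingPairs(training)$similarity
  w <- e$weight[match(keys, key)]
  expect_equal(abs(cor(w, s)), achievedPcc(cf), tolerance = 1e-8)
})

test_that("rescaled integration lands in [0, 1]", {
  training <- makeTraining(paste0("a", 1:4), paste0("b", 1:4),
    c(0.1, 0.4, 0.6, 0.9))
  keys <- ontonet:::.pairKey(paste0("a", 1:4), paste0("b", 1:4))
  net <- makeNetwork(paste0("a", 1:4), paste0("b", 1:4),
    c(0.2, 0.4, 0.6, 0.8), name = "n1")
  map <- makeMap(keys, c(0.2, 0.4, 0.6, 0.8), 1:4, c(0.1, 0.4, 0.6, 0.9))
  cf <- fitIntegration(buildDesignMatrix(list(net), list(map), training),
    trainingPairs(training)$similarity)
  integ <- integrateNetworks(list(net), list(map), cf)
  expect_true(all(networkEdges(integ)$weight >= 0 &
    networkEdges(integ)$weight <= 1))
})
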