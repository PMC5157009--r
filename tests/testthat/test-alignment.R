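test_that("term similarity is the Jaccard index", {
  expect_equal(termSimilarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(termSimilarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(termSimilarity(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(termSimilarity(character(), "a"), "non-empty")
})

test_that("self-alignment is the identity at score 1", {
  dag <- randomInferred(12, 6, seed = 2)
  al <- alignOntologies(dag, dag, nPerm = 30, seed = 1, minGenes = 2,
    maxGeneFrac = 1)
  p <- alignedPairs(al)
  keep <- names(termGenes(dag))[lengths(termGenes(dag)) >= 2]
  expect_setequal(p$termX, keep)
  expect_equal(p$termX, p$termY)
  expect_true(all(p$score == 1))
  expect_lt(fdrThreshold(al), 1 + 1e-9)
})

test_that("disjoint gene universes give an empty alignment", {
  a <- makeInferred(list(TA = c("a1", "a2")))
  b <- makeInferred(list(TB = c("b1", "b2")))
  expect_warning(al <- alignOntologies(a, b, nPerm = 10), "shared")
  expect_equal(nrow(alignedPairs(al)), 0L)
})

test_that("greedy matching resolves ambiguity toward the higher score", {
  # one x-term matches two y-terms; the best-scoring pair must win, and
  # exhaustive search over one-to-one matchings confirms optimality here
  genes <- paste0("g", 1:6)
  x <- list(X1 = genes[1:4], X2 = genes[5:6])
  y <- list(Y1 = genes[1:3], Y2 = genes[1:4], Y3 = genes[4:6])
  sx <- ontonet:::.scoreMatrix(x, y, genes)
  m <- ontonet:::.greedyMatch(sx,
    list(X1 = character(), X2 = character()),
    list(Y1 = character(), Y2 = character(), Y3 = character()),
    c(X1 = 4, X2 = 2))
  expect_equal(m$termY[m$termX == "X1"], "Y2")   # score 1 beats 3/4

  # exhaustive oracle over all one-to-one matchings
  best <- -Inf; bestSum <- NULL
  for (p1 in c("Y1", "Y2", "Y3", NA)) for (p2 in c("Y1", "Y2", "Y3", NA)) {
    if (!is.na(p1) && !is.na(p2) && p1 == p2) next
    tot <- sum(c(if (!is.na(p1)) sx["X1", p1],
      if (!is.na(p2)) sx["X2", p2]))
    if (tot > best) best <- tot
  }
  expect_equal(sum(m$score), best)
})

test_that("alignments are one-to-one and never crisscross", {
  for (sd in 1:10) {
    x <- randomInferred(15, 7, seed = sd)
    y <- randomInferred(15, 6, seed = sd + 100)
    al <- alignOntologies(x, y, nPerm = 20, seed = sd, minGenes = 2,
      maxGeneFrac = 1)
    p <- alignedPairs(al)
    expect_true(validObject(al))
    if (nrow(p) < 2L) next
    ancX <- ontonet:::.dagGeneSets(x, minGenes = 1)$ancestors
    ancY <- ontonet:::.dagGeneSets(y, minGenes = 1)$ancestors
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(p))) {
      if (i == j) next
      xAnc <- p$termX[j] %in% ancX[[p$termX[i]]]
      yDes <- p$termY[i] %in% ancY[[p$termY[j]]]
      expect_false(xAnc && yDes)
    }
  }
})

test_that("permuted-label nulls are controlled at the FDR", {
  # align structured DAGs against label-permuted copies: essentially no
  # pair should survive the 5% cutoff
  retained <- 0L; matched <- 0L
  for (sd in 1:15) {
    x <- randomInferred(14, 6, seed = sd)
    set.seed(sd + 500)
    genes <- sort(unique(unlist(termGenes(x))))
    perm <- setNames(sample(genes), genes)
    ys <- lapply(termGenes(x)[lengths(termGenes(x)) >= 2],
      function(g) sort(unname(perm[g])))
    names(ys) <- paste0("Y", seq_along(ys))
    y <- makeInferred(ys)
    al <- alignOntologies(x, y, fdr = 0.05, nPerm = 40, seed = sd,
      minGenes = 2, maxGeneFrac = 1)
    retained <- retained + nrow(alignedPairs(al))
    matched <- matched + length(termGenes(y)[lengths(termGenes(y)) >= 2])
  }
  # binomial 95% bound around 0.05
  bound <- 0.05 + 1.96 * sqrt(0.05 * 0.95 / matched)
  expect_lte(retained / matched, bound)
})

test_that("training-derived flags read off the alignment", {
  empty <- new("AlignmentResult", pairs = data.frame(termX = character(),
    termY = character(), score = numeric(), stringsAsFactors = FALSE),
    fdrThreshold = Inf, nPerm = 10L)
  expect_length(flagTrainingDerived(empty), 0L)
  al <- new("AlignmentResult", pairs = data.frame(
    termX = c("A", "B"), termY = c("T1", "T2"), score = c(1, 0.8),
    stringsAsFactors = FALSE), fdrThreshold = 0.5, nPerm = 10L)
  expect_setequal(flagTrainingDerived(al), c("A", "B"))
})

test_that("evaluation metrics follow their formulas", {
  al <- new("AlignmentResult", pairs = data.frame(
    termX = paste0("X", 1:5), termY = paste0("R", 1:5),
    score = rep(1, 5), stringsAsFactors = FALSE),
    fdrThreshold = 0.5, nPerm = 10L)
  ref <- paste0("R", 1:10)
  m <- evaluateAlignment(al, ref, trainingTerms = character(),
    trainingDerived = character(), inferredTermCount = 5L)
  expect_equal(m@hit, 5L)
  expect_equal(m@precision, 1)
  expect_equal(m@recall, 0.5)
  expect_equal(m@fMeasure, 2 / 3)

  # aligned reference terms inside the training part do not count
  m2 <- evaluateAlignment(al, ref, trainingTerms = paste0("R", 1:5),
    trainingDerived = character(), inferredTermCount = 5L)
  expect_equal(m2@hit, 0L)
  expect_equal(m2@fMeasure, 0)

  # training-derived inferred terms are excluded from both sides
  m3 <- evaluateAlignment(al, ref, trainingTerms = character(),
    trainingDerived = c("X1", "X2"), inferredTermCount = 5L)
  expect_equal(m3@hit, 3L)
  expect_equal(m3@precision, 1)

  expect_error(evaluateAlignment(al, paste0("R", 1:5), paste0("R", 1:5),
    character(), 5L), "recall")
})
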