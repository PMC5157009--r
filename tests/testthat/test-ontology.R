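test_that("OBO parsing builds the expected DAG structures", {
  dag <- loadOntology(chainObo(), "toy")
  expect_s4_class(dag, "OntologyDAG")
  expect_setequal(termIds(dag), c("A", "B", "C"))
  expect_equal(nrow(parentLinks(dag)), 2L)
  expect_equal(rootTerms(dag), "A")

  dia <- loadOntology(diamondObo(), "toy")
  pl <- parentLinks(dia)
  expect_setequal(pl$parent[pl$child == "D"], c("B", "C"))
})

test_that("OBO parsing rejects cycles and unknown namespaces", {
  cyc <- makeOboFile(c(
    "[Term]", "id: A", "namespace: toy", "is_a: B", "",
    "[Term]", "id: B", "namespace: toy", "is_a: A"))
  expect_error(loadOntology(cyc, "toy"), "cycle")
  expect_error(loadOntology(chainObo(), "nope"), "toy")
})

test_that("obsolete terms are dropped and alt ids resolved", {
  obo <- makeOboFile(c(
    "[Term]", "id: A", "namespace: toy", "",
    "[Term]", "id: B", "namespace: toy", "alt_id: Bold", "is_a: A", "",
    "[Term]", "id: Z", "namespace: toy", "is_a: A", "is_obsolete: true"))
  dag <- loadOntology(obo, "toy")
  expect_setequal(termIds(dag), c("A", "B"))
  ann <- propagateAnnotations(dag, list(g1 = "Bold"))
  expect_setequal(propagatedAnnotations(ann)$g1, c("A", "B"))
})

test_that("ontology round-trips through writeObo", {
  dag <- loadOntology(diamondObo(), "toy")
  path <- tempfile(fileext = ".obo")
  writeObo(dag, path)
  dag2 <- loadOntology(path, "toy")
  expect_setequal(termIds(dag2), termIds(dag))
  expect_equal(
    parentLinks(dag2)[order(parentLinks(dag2)$child,
      parentLinks(dag2)$parent), ],
    parentLinks(dag)[order(parentLinks(dag)$child,
      parentLinks(dag)$parent), ],
    ignore_attr = TRUE)
})

test_that("annotation propagation covers ancestors and is idempotent", {
  dag <- loadOntology(chainObo(), "toy")
  ann <- propagateAnnotations(dag, list(g1 = "C", g2 = "A"))
  expect_setequal(propagatedAnnotations(ann)$g1, c("A", "B", "C"))
  expect_equal(propagatedAnnotations(ann)$g2, "A")

  dia <- loadOntology(diamondObo(), "toy")
  annD <- propagateAnnotations(dia, list(g = "D"))
  expect_setequal(propagatedAnnotations(annD)$g, c("A", "B", "C", "D"))

  # idempotence: propagating the propagated sets changes nothing
  again <- propagateAnnotations(dia, propagatedAnnotations(annD))
  expect_identical(propagatedAnnotations(again),
    propagatedAnnotations(annD))

  expect_warning(propagateAnnotations(dag, list(g1 = c("C", "GHOST"))),
    "skipped")
})

test_that("training sub-tree selection follows shortest-path levels", {
  # chain of 6 terms, root level 1 -> sub-tree roots at levels 2-5
  chain <- makeDag(data.frame(child = paste0("T", 2:6),
    parent = paste0("T", 1:5), stringsAsFactors = FALSE))
  expect_setequal(selectTrainingSubtrees(chain), paste0("T", 2:5))

  twoLevel <- makeDag(data.frame(child = c("L1", "L2"),
    parent = c("R", "R"), stringsAsFactors = FALSE))
  expect_setequal(selectTrainingSubtrees(twoLevel), c("L1", "L2"))

  single <- makeDag(data.frame(child = character(), parent = character(),
    stringsAsFactors = FALSE), ids = "R")
  expect_length(selectTrainingSubtrees(single), 0L)

  # a diamond child reached by two paths takes the shorter one
  dia <- loadOntology(diamondObo(), "toy")
  expect_equal(unname(termLevels(dia)[c("A", "B", "D")]), c(1L, 2L, 3L))
})

test_that("Resnik similarity matches its closed form", {
  w <- sixGeneWorld()
  ts <- trainingPairSimilarities(w$dag, "R", w$annotations)
  p <- trainingPairs(ts)
  lookup <- function(a, b)
    p$similarity[p$geneA == min(a, b) & p$geneB == max(a, b)]
  # deepest shared term XZ annotates 2 of 6 genes
  expect_equal(lookup("g1", "g2"), log(6 / 2) / log(6))
  # shared term X annotates 3 of 6
  expect_equal(lookup("g1", "g3"), log(6 / 3) / log(6))
  # only the root shared -> 0
  expect_equal(lookup("g1", "g4"), 0)
  expect_equal(nrow(p), choose(6, 2))

  # |G_tot| = 8, |G_LCA| = 2 closed form via resnikSimilarity directly
  restricted <- c(list(a = c("R", "S"), b = c("R", "S")),
    setNames(rep(list("R"), 6), paste0("x", 1:6)))
  expect_equal(resnikSimilarity(restricted, "a", "b"), log(8 / 2) / log(8))
})

test_that("Resnik similarity equals brute-force max-IC over ancestors", {
  w <- sixGeneWorld()
  sub <- ontonet:::.restrictAnnotations(w$annotations,
    trainingSubtreeTerms(w$dag, "R"))
  counts <- table(unlist(sub))
  genes <- names(sub)
  ts <- trainingPairSimilarities(w$dag, "R", w$annotations)
  p <- trainingPairs(ts)
  for (r in seq_len(nrow(p))) {
    common <- intersect(sub[[p$geneA[r]]], sub[[p$geneB[r]]])
    brute <- max(vapply(common, function(t)
      log(length(genes) / counts[[t]]) / log(length(genes)), numeric(1)))
    expect_equal(p$similarity[r], brute)
  }
})

test_that("Resnik score is symmetric and anti-monotone in |G_LCA|", {
  nTot <- 12
  scores <- vapply(2:12, function(nLca) log(nTot / nLca) / log(nTot),
    numeric(1))
  expect_true(all(diff(scores) < 0))

  w <- sixGeneWorld()
  sub <- ontonet:::.restrictAnnotations(w$annotations,
    trainingSubtreeTerms(w$dag, "R"))
  expect_equal(resnikSimilarity(sub, "g1", "g5"),
    resnikSimilarity(sub, "g5", "g1"))
  expect_error(resnikSimilarity(sub, "g1", "g1"), "distinct")
  expect_error(resnikSimilarity(sub, "g1", "nope"), "annotation")
})

test_that("degenerate training parts are handled", {
  # all genes annotated only to the training root -> all scores 0
  dag <- makeDag(data.frame(child = "S", parent = "R",
    stringsAsFactors = FALSE))
  ann <- propagateAnnotations(dag,
    setNames(rep(list("S"), 4), paste0("g", 1:4)))
  ts <- trainingPairSimilarities(dag, "S", ann)
  expect_equal(nrow(trainingPairs(ts)), 6L)
  expect_true(all(trainingPairs(ts)$similarity == 0))
  expect_equal(sum(trainingPairs(ts)$similar), 0L)

  ann1 <- propagateAnnotations(dag, list(g1 = "S"))
  expect_error(trainingPairSimilarities(dag, "S", ann1), "fewer than 2")
})
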