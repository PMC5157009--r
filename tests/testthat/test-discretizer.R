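test_that("discordance counts disagreeing unordered pairs", {
  # all pairs in one level, equal similarities -> 0
  expect_equal(ontonet:::.discordanceVec(c(1L, 1L, 1L), c(0.5, 0.5, 0.5)),
    0L)
  # one level, 3 distinct similarities -> every unordered pair discordant
  expect_equal(ontonet:::.discordanceVec(c(1L, 1L, 1L), c(0.1, 0.2, 0.3)),
    3L)
  # levels perfectly rank-matching similarities -> 0
  expect_equal(ontonet:::.discordanceVec(1:4, c(0.1, 0.2, 0.3, 0.4)), 0L)
  # invariant to strictly increasing relabeling of levels
  lev <- c(1L, 1L, 2L, 3L); s <- c(0.3, 0.1, 0.2, 0.4)
  expect_equal(ontonet:::.discordanceVec(lev, s),
    ontonet:::.discordanceVec(c(2L, 2L, 5L, 9L), s))
})

test_that("discordance() accepts a map and cross-checks the training set", {
  training <- makeTraining(paste0("a", 1:4), paste0("b", 1:4),
    c(0.1, 0.2, 0.3, 0.4))
  w <- setNames(c(1, 2, 3, 4),
    ontonet:::.pairKey(paste0("a", 1:4), paste0("b", 1:4)))
  map <- searchDiscretization(w, training, searchParams(k = 4, seed = 1))
  expect_equal(discordance(map), objectiveValue(map))
  expect_equal(discordance(map, training), objectiveValue(map))
})

test_that("search returns optimum on concordant and degenerate input", {
  training <- makeTraining(paste0("a", 1:5), paste0("b", 1:5),
    c(0.1, 0.2, 0.3, 0.4, 0.5))
  keys <- ontonet:::.pairKey(paste0("a", 1:5), paste0("b", 1:5))
  # weights already rank-concordant -> objective 0 attainable
  map <- searchDiscretization(setNames(1:5 / 5, keys), training,
    searchParams(k = 5, maxIterations = 500, seed = 1))
  expect_equal(objectiveValue(map), 0)

  # all weights equal -> single level, objective directly computable
  map1 <- searchDiscretization(setNames(rep(0.4, 5), keys), training,
    searchParams(seed = 1))
  expect_equal(nLevels(map1), 1L)
  expect_equal(objectiveValue(map1), choose(5, 2))
})

test_that("search respects order preservation and seed determinism", {
  set.seed(42)
  n <- 12
  training <- makeTraining(paste0("a", 1:n), paste0("b", 1:n), runif(n))
  keys <- ontonet:::.pairKey(paste0("a", 1:n), paste0("b", 1:n))
  w <- setNames(sample(c(0.2, 0.4, 0.4, runif(n - 3))), keys)
  m1 <- searchDiscretization(w, training,
    searchParams(k = 4, maxIterations = 800, restarts = 2, seed = 7))
  m2 <- searchDiscretization(w, training,
    searchParams(k = 4, maxIterations = 800, restarts = 2, seed = 7))
  expect_identical(m1@levels, m2@levels)
  expect_true(validObject(m1))
  # order preservation, explicitly
  o <- order(m1@weights)
  expect_false(is.unsorted(m1@levels[o]))
  # equal weights share a level
  eq <- which(m1@weights == 0.4)
  expect_length(unique(m1@levels[eq]), 1L)
  # tracked objective equals a full recount
  expect_equal(objectiveValue(m1),
    ontonet:::.discordanceVec(m1@levels, m1@similarities))
})

test_that("search matches the exhaustive enumeration oracle", {
  hits <- 0L; total <- 20L
  for (sd in seq_len(total)) {
    set.seed(sd)
    n <- sample(4:8, 1)
    sims <- round(runif(n), 2)
    weights <- round(runif(n), 2)
    training <- makeTraining(paste0("a", 1:n), paste0("b", 1:n), sims)
    keys <- ontonet:::.pairKey(paste0("a", 1:n), paste0("b", 1:n))
    map <- searchDiscretization(setNames(weights, keys), training,
      searchParams(k = 4, maxIterations = 2000, restarts = 5, seed = sd))
    oracle <- bruteForceDiscretization(weights, sims, k = 4)
    expect_gte(objectiveValue(map), oracle)
    if (objectiveValue(map) == oracle) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * total))
})

test_that("level merging lands in the target range and preserves order", {
  set.seed(11)
  n <- 60
  training <- makeTraining(paste0("a", 1:n), paste0("b", 1:n), runif(n))
  keys <- ontonet:::.pairKey(paste0("a", 1:n), paste0("b", 1:n))
  w <- setNames(runif(n), keys)
  map <- searchDiscretization(w, training,
    searchParams(k = 40, maxIterations = 200, seed = 3))
  merged <- mergeLevels(map, 10L, 20L)
  expect_lte(nLevels(merged), 20L)
  expect_gte(nLevels(merged), 10L)
  expect_true(validObject(merged))
  expect_equal(objectiveValue(merged),
    ontonet:::.discordanceVec(merged@levels, merged@similarities))

  # a map already in range is unchanged
  small <- searchDiscretization(w[1:5], training,
    searchParams(k = 5, maxIterations = 100, seed = 1))
  expect_identical(mergeLevels(small), small)
})

test_that("merging prefers the adjacent pair costing least discordance", {
  # 4 hand-built levels; the top two share identical similarities, so
  # merging them is the cheapest move (here it even removes discordance)
  sims <- c(0.1, 0.2, 0.5, 0.5, 0.5, 0.5)
  w <- c(0.1, 0.2, 0.5, 0.55, 0.8, 0.85)
  keys <- ontonet:::.pairKey(paste0("a", 1:6), paste0("b", 1:6))
  lev <- c(1L, 2L, 3L, 3L, 4L, 4L)
  map <- ontonet:::.mapFromLevels(keys, w, sims, lev, 4L,
    ontonet:::.discordanceVec(lev, sims))
  merged <- mergeLevels(map, 1L, 3L)
  expect_equal(nLevels(merged), 3L)
  # greedy replay: costs are +1 (levels 1|2), +2 (2|3), -4 (3|4)
  expect_equal(objectiveValue(merged), objectiveValue(map) - 4)
  lv <- merged@levels
  expect_equal(lv[3], lv[5])   # the old levels 3 and 4 are now one
  expect_true(validObject(merged))
})

test_that("applying a map discretizes training and non-training edges", {
  training <- makeTraining(paste0("a", 1:4), paste0("b", 1:4),
    c(0.1, 0.2, 0.6, 0.9))
  keys <- ontonet:::.pairKey(paste0("a", 1:4), paste0("b", 1:4))
  w <- setNames(c(0.1, 0.2, 0.7, 0.9), keys)
  map <- searchDiscretization(w, training,
    searchParams(k = 2, maxIterations = 500, seed = 1))
  genes <- c(sort(c(paste0("a", 1:4), paste0("b", 1:4))), "x", "y", "z")
  net <- makeNetwork(
    c(paste0("a", 1:4), "x", "x", "y"),
    c(paste0("b", 1:4), "y", "z", "z"),
    c(0.1, 0.2, 0.7, 0.9, 0.2, 0.45, 2.0), genes = genes)
  disc <- applyDiscretization(map, net)
  e <- networkEdges(disc)
  key <- ontonet:::.pairKey(e$geneA, e$geneB)
  lw <- levelWeights(map)
  # training edges get their own level's mean weight
  expect_equal(e$weight[key == keys[1]],
    lw[map@levels[map@pairKeys == keys[1]]])
  # a non-training edge equal to a training weight joins that level
  expect_equal(e$weight[key == ontonet:::.pairKey("x", "y")],
    e$weight[key == keys[2]])
  # a weight between two training weights takes the lower level
  lvlOf <- function(k) which(lw == e$weight[key == k])
  expect_equal(lvlOf(ontonet:::.pairKey("x", "z")),
    unname(map@levels[map@pairKeys == keys[2]]))
  # beyond the top boundary -> top level
  expect_equal(e$weight[key == ontonet:::.pairKey("y", "z")], max(lw))
  expect_true(all(e$weight %in% lw))
})
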