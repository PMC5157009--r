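#' Search parameters for the discretization search
#'
#' @param k initial number of ordered levels (default 200).
#' @param maxIterations iterations per restart (default 10000).
#' @param restarts number of random restarts (default 5).
#' @param seed RNG seed making the search reproducible.
#' @return a [SearchParams-class].
#' @export
searchParams <- function(k = 200L, maxIterations = 10000L, restarts = 5L,
                         seed = 1L) {
  new("SearchParams", k = as.integer(k),
    maxIterations = as.integer(maxIterations),
    restarts = as.integer(restarts), seed = as.integer(seed))
}

# direction function: sign of x - y
.direction <- function(x, y) sign(x - y)

# full-recount discordance between level assignment and similarities,
# counted over unordered pairs of training pairs
.discordanceVec <- function(levels, sims) {
  dl <- sign(outer(levels, levels, "-"))
  ds <- sign(outer(sims, sims, "-"))
  sum((dl != ds)[upper.tri(dl)])
}

#' Discordance of a discretization with the ontological similarities
#'
#' Counts, over unordered pairs \{p, q\} of training gene pairs, how often
#' the direction of their discretized levels disagrees with the direction
#' of their ontological similarities, where the direction function is
#' d(x, y) = 1 if x > y, 0 if x = y and -1 if x < y. This is the objective
#' the discretization search minimizes.
#'
#' @param map a [DiscretizationMap-class].
#' @param training optional [TrainingSet-class]; when supplied, the
#'   similarities are looked up there instead of the map's stored copy.
#' @return a non-negative integer count.
#' @export
discordance <- function(map, training = NULL) {
  sims <- map@similarities
  if (!is.null(training)) {
    p <- training@pairs
    sims <- setNames(p$similarity, .pairKey(p$geneA, p$geneB))[map@pairKeys]
    if (anyNA(sims)) stop("map covers pairs missing from the training set")
    sims <- unname(sims)
  }
  .discordanceVec(map@levels, sims)
}

# Precompute, per ordered group pair (g < h by weight), the change in
# discordance when g and h share a level instead of sitting in different
# levels. For p in g, q in h (w_p < w_q): different levels are discordant
# iff s_p >= s_q; equal levels iff s_p != s_q. D[g, h] = cSame - cDiff.
# The objective is then  constant + sum over levels of within-level D,
# which makes move evaluation O(affected groups) -- the incremental scheme.
.groupStructure <- function(weights, sims) {
  o <- order(weights)
  w <- weights[o]; s <- sims[o]
  grp <- cumsum(c(TRUE, diff(w) > 0))
  m <- max(grp)
  G <- matrix(0, length(w), m)
  G[cbind(seq_along(w), grp)] <- 1
  Sge <- outer(s, s, ">=") * 1
  Sne <- outer(s, s, "!=") * 1
  cDiff <- t(G) %*% Sge %*% G
  cSame <- t(G) %*% Sne %*% G
  D <- cSame - cDiff                     # use [g, h] with g < h only
  ut <- upper.tri(cDiff)
  baseConst <- sum(diag(cSame)) / 2 + sum(cDiff[ut])
  list(order = o, grp = grp, m = m, D = D, baseConst = baseConst,
    groupWeights = w[!duplicated(grp)])
}

# objective of a non-decreasing group->level assignment
.blockObjective <- function(lev, st) {
  obj <- st$baseConst
  for (l in unique(lev)) {
    idx <- which(lev == l)
    if (length(idx) > 1L)
      obj <- obj + sum(st$D[idx, idx][upper.tri(diag(length(idx)))])
  }
  obj
}

.mapFromLevels <- function(pairKeys, weights, sims, lev, kInitial,
                           objective) {
  lev <- as.integer(factor(lev, levels = sort(unique(lev))))
  levelWeights <- as.numeric(tapply(weights, lev, mean))
  boundaries <- as.numeric(tapply(weights, lev, min))
  new("DiscretizationMap", pairKeys = pairKeys, weights = weights,
    levels = lev, levelWeights = levelWeights, boundaries = boundaries,
    similarities = sims, kInitial = as.integer(kInitial),
    objective = objective)
}

#' Stochastic search for an order-preserving discretization
#'
#' Partitions the training-pair edge weights of one network into at most
#' \code{k} ordered levels minimizing the [discordance()] objective,
#' subject to order preservation (higher weight never gets a lower level;
#' equal weights share a level). Starting from a random order-preserving
#' partition, the search repeatedly proposes moving a block of 1-5
#' top (or bottom) equal-weight groups of a random level into the adjacent
#' level. Improving moves are always accepted; others are accepted with
#' probability \code{min(0.1 / iteration, 0.001)}, an annealing-like
#' schedule. The best map over all iterations and restarts is returned;
#' the whole procedure is deterministic given the seed.
#'
#' @param weights named numeric vector: training-pair edge weights, names
#'   are canonical "geneA|geneB" keys.
#' @param training a [TrainingSet-class] supplying the similarities.
#' @param params a [SearchParams-class].
#' @return a [DiscretizationMap-class].
#' @export
searchDiscretization <- function(weights, training,
                                 params = searchParams()) {
  if (length(weights) < 2L)
    stop("need at least 2 training pairs with an edge")
  p <- training@pairs
  simLookup <- setNames(p$similarity, .pairKey(p$geneA, p$geneB))
  if (!all(names(weights) %in% names(simLookup)))
    stop("weights contain pairs missing from the training set")
  sims <- unname(simLookup[names(weights)])

  st <- .groupStructure(weights, sims)
  keys <- names(weights)[st$order]
  w <- unname(weights[st$order])
  s <- sims[st$order]
  m <- st$m
  k <- min(params@k, m)

  if (m == 1L) {                         # all weights identical
    lev <- rep(1L, length(w))
    return(.mapFromLevels(keys, w, s, lev,
      params@k, .discordanceVec(lev, s)))
  }

  set.seed(params@seed)
  bestLev <- NULL
  bestObj <- Inf
  for (r in seq_len(params@restarts)) {
    lev <- if (m <= k) seq_len(m) else {
      cuts <- sort(sample.int(m - 1L, k - 1L))
      rep(seq_len(k), diff(c(0L, cuts, m)))
    }
    obj <- .blockObjective(lev, st)
    if (obj < bestObj) { bestObj <- obj; bestLev <- lev }
    kMax <- max(lev)
    for (it in seq_len(params@maxIterations)) {
      occ <- unique(lev)
      a <- occ[sample.int(length(occ), 1L)]
      blk <- which(lev == a)
      t <- sample.int(min(5L, length(blk)), 1L)
      up <- runif(1) < 0.5
      if (up) {
        if (a >= kMax) next
        S <- blk[seq.int(length(blk) - t + 1L, length(blk))]
        remain <- setdiff(blk, S)
        target <- which(lev == a + 1L)
        delta <- sum(st$D[remain, S]) * -1 + sum(st$D[S, target])
        newLevel <- a + 1L
      } else {
        if (a <= 1L) next
        S <- blk[seq_len(t)]
        remain <- setdiff(blk, S)
        target <- which(lev == a - 1L)
        delta <- sum(st$D[S, remain]) * -1 + sum(st$D[target, S])
        newLevel <- a - 1L
      }
      if (delta < 0 || runif(1) < min(0.1 / it, 0.001)) {
        lev[S] <- newLevel
        obj <- obj + delta
        if (obj < bestObj) { bestObj <- obj; bestLev <- lev }
      }
    }
  }
  levPairs <- bestLev[st$grp]
  map <- .mapFromLevels(keys, w, s, levPairs, params@k, bestObj)
  stopifnot(abs(map@objective - .discordanceVec(map@levels, s)) < 0.5)
  map
}

#' Merge adjacent discretization levels down to a target range
#'
#' Maps with more than \code{targetMax} levels are coarsened to avoid
#' over-fitting in the integration step: the adjacent level pair whose
#' merge least increases the discordance objective is merged greedily
#' (ties broken toward the smaller combined size, then the lower pair)
#' until the level count is at most \code{targetMax}. Maps already within
#' range are returned unchanged.
#'
#' @param map a [DiscretizationMap-class].
#' @param targetMin,targetMax desired level-count range (defaults 10, 20).
#' @return a [DiscretizationMap-class].
#' @export
mergeLevels <- function(map, targetMin = 10L, targetMax = 20L) {
  lev <- map@levels
  nl <- length(unique(lev))
  if (nl <= targetMax) return(map)
  s <- map@similarities
  obj <- map@objective
  # cost of merging adjacent levels j, j+1: for p in j, q in j+1
  # (w_p < w_q), discordance changes by #[s_p < s_q] - #[s_p == s_q]
  mergeCost <- function(lo, hi) {
    slo <- s[lev == lo]; shi <- s[lev == hi]
    lt <- outer(slo, shi, "<")
    eq <- outer(slo, shi, "==")
    sum(lt) - sum(eq)
  }
  while (length(unique(lev)) > targetMax) {
    occ <- sort(unique(lev))
    costs <- vapply(seq_len(length(occ) - 1L), function(i)
      mergeCost(occ[i], occ[i + 1L]), numeric(1))
    sizes <- vapply(seq_len(length(occ) - 1L), function(i)
      sum(lev %in% occ[c(i, i + 1L)]), numeric(1))
    best <- order(costs, sizes, seq_along(costs))[1L]
    lev[lev == occ[best + 1L]] <- occ[best]
    obj <- obj + costs[best]
  }
  .mapFromLevels(map@pairKeys, map@weights, s, lev, map@kInitial, obj)
}

#' Discretize every edge of a network with a learned map
#'
#' Every edge, training or not, is assigned to the level whose half-open
#' weight interval contains its original weight (level j spans
#' \code{[boundaries[j], boundaries[j + 1])}; weights below the bottom
#' boundary take level 1, weights at or above the top boundary take the top
#' level), and receives that level's representative weight (the mean of the
#' member training-pair weights).
#'
#' @param map a [DiscretizationMap-class].
#' @param net a [WeightedNetwork-class] (typically the filtered network the
#'   map was learned on).
#' @return a [WeightedNetwork-class] with discretized weights.
#' @export
applyDiscretization <- function(map, net) {
  e <- net@edges
  if (nrow(e) == 0L) return(net)
  lvl <- pmax(findInterval(e$weight, map@boundaries), 1L)
  e$weight <- map@levelWeights[lvl]
  new("WeightedNetwork", edges = e, genes = net@genes,
    name = paste0(net@name, "_disc"))
}

# level index of arbitrary weights under a map's boundaries
.levelIndex <- function(map, w) {
  pmax(findInterval(w, map@boundaries), 1L)
}

#' Write a discretization report
#'
#' One row per level: boundaries, representative weight, member count.
#'
#' @param map a [DiscretizationMap-class].
#' @param path output file (tab-separated).
#' @return the path, invisibly.
#' @export
writeDiscretizationReport <- function(map, path) {
  df <- data.frame(level = seq_along(map@levelWeights),
    lowerBoundary = map@boundaries,
    levelWeight = map@levelWeights,
    members = as.integer(table(map@levels)),
    stringsAsFactors = FALSE)
  attr(df, "objective") <- map@objective
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# discordance objective: %d",
    as.integer(map@objective)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
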