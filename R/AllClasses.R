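#' @import methods
#' @importFrom stats cor rnorm runif setNames quantile
#' @importFrom utils head tail read.delim write.table
NULL

#' OntologyDAG: a rooted directed acyclic graph of ontology terms
#'
#' Terms are nodes; \code{parentLinks} holds child -> parent edges
#' (\code{is_a} and \code{part_of} collapsed). Roots are terms with no
#' parent. Multiple parents are allowed; cycles are not.
#'
#' @slot termIds character vector of term identifiers.
#' @slot termNames named character vector of human-readable names (may be
#'   empty).
#' @slot parentLinks data.frame with columns \code{child}, \code{parent}.
#' @slot namespace single character label for the sub-ontology.
#' @slot altIds named character vector mapping alternative ids to primary
#'   ids (used to resolve annotations).
#' @exportClass OntologyDAG
setClass("OntologyDAG",
  representation(
    termIds = "character",
    termNames = "character",
    parentLinks = "data.frame",
    namespace = "character",
    altIds = "character"
  ),
  prototype(
    termIds = character(), termNames = character(),
    parentLinks = data.frame(child = character(), parent = character(),
      stringsAsFactors = FALSE),
    namespace = NA_character_, altIds = character()
  )
)

setValidity("OntologyDAG", function(object) {
  pl <- object@parentLinks
  msg <- character()
  if (!all(c("child", "parent") %in% names(pl)))
    msg <- c(msg, "parentLinks must have columns 'child' and 'parent'")
  else {
    if (!all(pl$child %in% object@termIds) ||
        !all(pl$parent %in% object@termIds))
      msg <- c(msg, "parentLinks refer to unknown terms")
    if (any(pl$child == pl$parent))
      msg <- c(msg, "self-links are not allowed")
    if (nrow(pl) > 0L) {
      g <- igraph::graph_from_data_frame(pl, directed = TRUE)
      if (!igraph::is_dag(g))
        msg <- c(msg, "parent relation contains a cycle")
    }
  }
  if (anyDuplicated(object@termIds))
    msg <- c(msg, "duplicated term ids")
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: gene-to-term annotations with upward closure
#'
#' @slot direct named list, gene -> character vector of directly annotated
#'   terms.
#' @slot propagated named list, gene -> direct terms plus all their
#'   ancestors in the ontology.
#' @slot nSkipped number of annotation records dropped because their term
#'   was unknown.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(direct = "list", propagated = "list",
    nSkipped = "integer"),
  prototype(direct = list(), propagated = list(), nSkipped = 0L)
)

setValidity("AnnotationSet", function(object) {
  if (!identical(sort(names(object@direct)), sort(names(object@propagated))))
    return("direct and propagated must cover the same genes")
  ok <- vapply(names(object@direct), function(g)
    all(object@direct[[g]] %in% object@propagated[[g]]), logical(1))
  if (!all(ok)) return("propagated sets must contain the direct sets")
  TRUE
})

#' TrainingSet: training gene pairs and their ontological similarity
#'
#' All unordered pairs of the training genes, with the normalized
#' simplified-Resnik similarity of each pair and the similarity threshold
#' t_s defining "semantically similar" pairs.
#'
#' @slot pairs data.frame with columns \code{geneA}, \code{geneB},
#'   \code{similarity}, \code{similar} (logical, similarity >= ts).
#' @slot genes character vector of training genes.
#' @slot ts similarity threshold (default 0.3).
#' @slot trainingRoot the term whose sub-tree defines the training part.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(pairs = "data.frame", genes = "character", ts = "numeric",
    trainingRoot = "character"),
  prototype(ts = 0.3, trainingRoot = NA_character_)
)

setValidity("TrainingSet", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("geneA", "geneB", "similarity") %in% names(p)))
    msg <- c(msg, "pairs needs columns geneA, geneB, similarity")
  else {
    if (any(p$geneA == p$geneB)) msg <- c(msg, "pairs must be distinct genes")
    if (any(p$similarity < -1e-12 | p$similarity > 1 + 1e-12))
      msg <- c(msg, "similarities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' WeightedNetwork: an undirected gene network with real edge weights
#'
#' Edges are stored canonically with \code{geneA < geneB}; at most one edge
#' per unordered pair, no self-loops, all weights finite.
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB},
#'   \code{weight}.
#' @slot genes the node universe (may include isolated genes).
#' @slot name free-text label.
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
  representation(edges = "data.frame", genes = "character",
    name = "character"),
  prototype(
    edges = data.frame(geneA = character(), geneB = character(),
      weight = numeric(), stringsAsFactors = FALSE),
    genes = character(), name = "network")
)

setValidity("WeightedNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("geneA", "geneB", "weight") %in% names(e)))
    return("edges needs columns geneA, geneB, weight")
  if (nrow(e) > 0L) {
    if (any(e$geneA == e$geneB)) msg <- c(msg, "self-loops not allowed")
    if (any(e$geneA > e$geneB))
      msg <- c(msg, "edges must be stored with geneA < geneB")
    if (anyDuplicated(paste(e$geneA, e$geneB, sep = "\r")))
      msg <- c(msg, "duplicate edges")
    if (any(!is.finite(e$weight))) msg <- c(msg, "non-finite weights")
    if (!all(c(e$geneA, e$geneB) %in% object@genes))
      msg <- c(msg, "edge endpoints missing from gene universe")
  }
  if (length(msg)) msg else TRUE
})

#' FilterResult: a learned edge-weight threshold and the filtered network
#'
#' @slot tw learned weight threshold (same units as the network weights).
#' @slot network the input network restricted to edges with weight >= tw.
#' @slot trainingFractionSimilar fraction of retained training edges that
#'   are semantically similar.
#' @slot fallbackUsed TRUE when the 50-percent requirement was never met and
#'   the early-stop fallback supplied the threshold.
#' @slot nEdgesBefore,nEdgesAfter edge counts before/after filtering.
#' @exportClass FilterResult
setClass("FilterResult",
  representation(tw = "numeric", network = "WeightedNetwork",
    trainingFractionSimilar = "numeric", fallbackUsed = "logical",
    nEdgesBefore = "integer", nEdgesAfter = "integer"))

#' SearchParams: knobs of the stochastic discretization search
#'
#' @slot k initial number of ordered levels (default 200).
#' @slot maxIterations iterations per restart (default 10000).
#' @slot restarts number of random restarts (default 5).
#' @slot seed RNG seed.
#' @exportClass SearchParams
setClass("SearchParams",
  representation(k = "integer", maxIterations = "integer",
    restarts = "integer", seed = "integer"),
  prototype(k = 200L, maxIterations = 10000L, restarts = 5L, seed = 1L))

setValidity("SearchParams", function(object) {
  if (object@k < 1L || object@maxIterations < 1L || object@restarts < 1L)
    return("k, maxIterations and restarts must be positive")
  TRUE
})

#' DiscretizationMap: an order-preserving partition of edge weights
#'
#' Training-pair edge weights are partitioned into ordered levels (level 1 =
#' smallest weights). Pairs with equal weight always share a level; the
#' representative weight of a level is the mean of its members' original
#' weights, and \code{boundaries[j]} is the smallest training weight in
#' level j (used as a half-open interval lower bound when discretizing
#' non-training edges).
#'
#' @slot pairKeys canonical "geneA|geneB" keys of the training pairs covered.
#' @slot weights original training-pair edge weights.
#' @slot levels integer level index per training pair (1 = lowest).
#' @slot levelWeights mean original weight per level, strictly increasing.
#' @slot boundaries lower weight bound per level, ascending.
#' @slot similarities ontological similarity per covered pair (kept so the
#'   discordance objective can be recomputed from the map alone).
#' @slot kInitial the initial level count used by the search.
#' @slot objective discordance of this map against the similarities.
#' @exportClass DiscretizationMap
setClass("DiscretizationMap",
  representation(pairKeys = "character", weights = "numeric",
    levels = "integer", levelWeights = "numeric", boundaries = "numeric",
    similarities = "numeric", kInitial = "integer", objective = "numeric"))

setValidity("DiscretizationMap", function(object) {
  msg <- character()
  n <- length(object@pairKeys)
  if (length(object@weights) != n || length(object@levels) != n ||
      length(object@similarities) != n)
    return("pairKeys, weights, levels, similarities must align")
  if (n > 0L) {
    o <- order(object@weights)
    if (is.unsorted(object@levels[o]))
      msg <- c(msg, "levels must be non-decreasing in weight")
    sp <- split(object@levels, object@weights)
    if (any(vapply(sp, function(x) length(unique(x)), integer(1)) > 1L))
      msg <- c(msg, "equal weights must share a level")
    if (any(diff(object@levelWeights) <= 0))
      msg <- c(msg, "level weights must be strictly increasing")
    if (length(object@levelWeights) != length(object@boundaries))
      msg <- c(msg, "levelWeights and boundaries must align")
  }
  if (length(msg)) msg else TRUE
})

#' DesignMatrix: training pairs by pooled discrete levels
#'
#' Row i / column (network, level j): the discretized edge weight of pair i
#' if its edge in that network falls in level j, else 0. Per network each
#' row has at most one non-zero entry.
#'
#' @slot M numeric matrix, |T| x N.
#' @slot columns data.frame with columns \code{network}, \code{level},
#'   \code{weight} describing each design column.
#' @slot pairKeys row identities ("geneA|geneB").
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(M = "matrix", columns = "data.frame",
    pairKeys = "character"))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@M) != length(object@pairKeys))
    return("row count must match pairKeys")
  if (ncol(object@M) != nrow(object@columns))
    return("column count must match columns metadata")
  for (net in unique(object@columns$network)) {
    sub <- object@M[, object@columns$network == net, drop = FALSE]
    if (any(rowSums(sub != 0) > 1L))
      return("a pair can occupy at most one level per network")
  }
  TRUE
})

#' CoefficientVector: the fitted linear integration of network levels
#'
#' @slot a unit-norm coefficient per design column, signed so the achieved
#'   correlation is non-negative.
#' @slot achievedPcc Pearson correlation of the combined score with the
#'   training similarities.
#' @slot columns design-column metadata (network, level, weight).
#' @exportClass CoefficientVector
setClass("CoefficientVector",
  representation(a = "numeric", achievedPcc = "numeric",
    columns = "data.frame"))

setValidity("CoefficientVector", function(object) {
  if (abs(sqrt(sum(object@a^2)) - 1) > 1e-6)
    return("coefficients must have unit Euclidean norm")
  if (object@achievedPcc < -1e-9 || object@achievedPcc > 1 + 1e-9)
    return("achievedPcc must lie in [0, 1]")
  TRUE
})

#' InferredDAG: a DAG of candidate terms, each a gene set
#'
#' Leaves are singleton genes; every internal term's gene set strictly
#' contains each of its children's gene sets.
#'
#' @slot termGenes named list, term -> character vector of genes.
#' @slot links data.frame with columns \code{child}, \code{parent}.
#' @slot birth named numeric, the weight threshold at which each internal
#'   term formed (NA for singleton leaves).
#' @slot alpha noise margin added to the edge-inclusion threshold.
#' @slot beta maximum tolerated fraction of missing edges in a term.
#' @exportClass InferredDAG
setClass("InferredDAG",
  representation(termGenes = "list", links = "data.frame",
    birth = "numeric", alpha = "numeric", beta = "numeric"))

setValidity("InferredDAG", function(object) {
  msg <- character()
  lk <- object@links
  if (nrow(lk) > 0L) {
    if (!all(c(lk$child, lk$parent) %in% names(object@termGenes)))
      return("links refer to unknown terms")
    g <- igraph::graph_from_data_frame(lk, directed = TRUE)
    if (!igraph::is_dag(g)) msg <- c(msg, "term DAG contains a cycle")
    for (i in seq_len(nrow(lk))) {
      cg <- object@termGenes[[lk$child[i]]]
      pg <- object@termGenes[[lk$parent[i]]]
      if (!(all(cg %in% pg) && length(cg) < length(pg))) {
        msg <- c(msg, "child gene sets must be strict subsets of parents")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' AlignmentResult: matched term pairs between two ontologies
#'
#' @slot pairs data.frame with columns \code{termX}, \code{termY},
#'   \code{score} (intrinsic gene-set similarity); one-to-one and free of
#'   ancestor/descendant crisscross.
#' @slot fdrThreshold the score cutoff realizing the requested FDR
#'   (Inf when nothing passed).
#' @slot nPerm number of gene-label permutations behind the null.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(pairs = "data.frame", fdrThreshold = "numeric",
    nPerm = "integer"))

setValidity("AlignmentResult", function(object) {
  p <- object@pairs
  if (nrow(p) > 0L &&
      (anyDuplicated(p$termX) || anyDuplicated(p$termY)))
    return("each term may appear in at most one aligned pair")
  TRUE
})

#' EvalMetrics: held-out evaluation of an inferred ontology
#'
#' @slot hit number of inferred terms aligned to reference terms outside the
#'   training part and not attributable to it.
#' @slot precision hit / (inferred terms - training-derived terms).
#' @slot recall hit / |reference terms outside the training part|.
#' @slot fMeasure harmonic mean of precision and recall (0 when hit = 0).
#' @exportClass EvalMetrics
setClass("EvalMetrics",
  representation(hit = "integer", precision = "numeric", recall = "numeric",
    fMeasure = "numeric"))

setValidity("EvalMetrics", function(object) {
  v <- c(object@precision, object@recall, object@fMeasure)
  if (any(v < -1e-12 | v > 1 + 1e-12))
    return("precision, recall and F must lie in [0, 1]")
  TRUE
})

#' SyntheticWorld: a planted ontology with annotations and noisy networks
#'
#' @slot dag the planted ontology.
#' @slot annotations gene annotations (direct at leaves, propagated up).
#' @slot networks list of WeightedNetwork, one per monotone transform.
#' @slot params generator parameters (transforms, noise, dropout, shape).
#' @slot seed the RNG seed the world was generated from.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(dag = "OntologyDAG", annotations = "AnnotationSet",
    networks = "list", params = "list", seed = "integer"))
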