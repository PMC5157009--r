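# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @export
setGeneric("rootTerms", function(x) standardGeneric("rootTerms"))
#' @export
setGeneric("parentLinks", function(x) standardGeneric("parentLinks"))
#' @export
setGeneric("ontologyNamespace", function(x) standardGeneric("ontologyNamespace"))
#' @export
setGeneric("directAnnotations", function(x) standardGeneric("directAnnotations"))
#' @export
setGeneric("propagatedAnnotations",
  function(x) standardGeneric("propagatedAnnotations"))
#' @export
setGeneric("trainingPairs", function(x) standardGeneric("trainingPairs"))
#' @export
setGeneric("trainingGenes", function(x) standardGeneric("trainingGenes"))
#' @export
setGeneric("similarityThreshold",
  function(x) standardGeneric("similarityThreshold"))
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))
#' @export
setGeneric("weightThreshold", function(x) standardGeneric("weightThreshold"))
#' @export
setGeneric("filteredNetwork", function(x) standardGeneric("filteredNetwork"))
#' @export
setGeneric("fallbackUsed", function(x) standardGeneric("fallbackUsed"))
#' @export
setGeneric("levelWeights", function(x) standardGeneric("levelWeights"))
#' @export
setGeneric("levelBoundaries", function(x) standardGeneric("levelBoundaries"))
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @export
setGeneric("designColumns", function(x) standardGeneric("designColumns"))
#' @export
setGeneric("integrationCoefficients",
  function(x) standardGeneric("integrationCoefficients"))
#' @export
setGeneric("achievedPcc", function(x) standardGeneric("achievedPcc"))
#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))
#' @export
setGeneric("dagLinks", function(x) standardGeneric("dagLinks"))
#' @export
setGeneric("birthThresholds", function(x) standardGeneric("birthThresholds"))
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
#' @export
setGeneric("fdrThreshold", function(x) standardGeneric("fdrThreshold"))
#' @export
setGeneric("worldNetworks", function(x) standardGeneric("worldNetworks"))
#' @export
setGeneric("worldOntology", function(x) standardGeneric("worldOntology"))
#' @export
setGeneric("worldAnnotations", function(x) standardGeneric("worldAnnotations"))

setMethod("termIds", "OntologyDAG", function(x) x@termIds)
setMethod("rootTerms", "OntologyDAG", function(x)
  setdiff(x@termIds, unique(x@parentLinks$child)))
setMethod("parentLinks", "OntologyDAG", function(x) x@parentLinks)
setMethod("ontologyNamespace", "OntologyDAG", function(x) x@namespace)

setMethod("directAnnotations", "AnnotationSet", function(x) x@direct)
setMethod("propagatedAnnotations", "AnnotationSet", function(x) x@propagated)

setMethod("trainingPairs", "TrainingSet", function(x) x@pairs)
setMethod("trainingGenes", "TrainingSet", function(x) x@genes)
setMethod("similarityThreshold", "TrainingSet", function(x) x@ts)

setMethod("networkEdges", "WeightedNetwork", function(x) x@edges)
setMethod("networkGenes", "WeightedNetwork", function(x) x@genes)

setMethod("weightThreshold", "FilterResult", function(x) x@tw)
setMethod("filteredNetwork", "FilterResult", function(x) x@network)
setMethod("fallbackUsed", "FilterResult", function(x) x@fallbackUsed)

setMethod("levelWeights", "DiscretizationMap", function(x) x@levelWeights)
setMethod("levelBoundaries", "DiscretizationMap", function(x) x@boundaries)
setMethod("nLevels", "DiscretizationMap", function(x)
  length(x@levelWeights))
setMethod("objectiveValue", "DiscretizationMap", function(x) x@objective)

setMethod("designMatrix", "DesignMatrix", function(x) x@M)
setMethod("designColumns", "DesignMatrix", function(x) x@columns)

setMethod("integrationCoefficients", "CoefficientVector", function(x) x@a)
setMethod("achievedPcc", "CoefficientVector", function(x) x@achievedPcc)

setMethod("termGenes", "InferredDAG", function(x) x@termGenes)
setMethod("dagLinks", "InferredDAG", function(x) x@links)
setMethod("birthThresholds", "InferredDAG", function(x) x@birth)

setMethod("alignedPairs", "AlignmentResult", function(x) x@pairs)
setMethod("fdrThreshold", "AlignmentResult", function(x) x@fdrThreshold)

setMethod("worldNetworks", "SyntheticWorld", function(x) x@networks)
setMethod("worldOntology", "SyntheticWorld", function(x) x@dag)
setMethod("worldAnnotations", "SyntheticWorld", function(x) x@annotations)

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG [%s]: %d terms, %d parent links, %d root(s)\n",
    object@namespace, length(object@termIds), nrow(object@parentLinks),
    length(rootTerms(object))))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf(
    "AnnotationSet: %d genes, %d direct / %d propagated annotations\n",
    length(object@direct), sum(lengths(object@direct)),
    sum(lengths(object@propagated))))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf(
    "TrainingSet [root %s]: %d genes, %d pairs, %d similar at t_s = %.2f\n",
    object@trainingRoot, length(object@genes), nrow(object@pairs),
    sum(object@pairs$similar), object@ts))
})

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@edges$weight
  cat(sprintf("WeightedNetwork '%s': %d genes, %d edges%s\n",
    object@name, length(object@genes), nrow(object@edges),
    if (length(w)) sprintf(", weights in [%.4g, %.4g]", min(w), max(w))
    else ""))
})

setMethod("show", "FilterResult", function(object) {
  cat(sprintf(
    "FilterResult: t_w = %.4g, %d -> %d edges, %.1f%% training edges similar%s\n",
    object@tw, object@nEdgesBefore, object@nEdgesAfter,
    100 * object@trainingFractionSimilar,
    if (object@fallbackUsed) " (fallback)" else ""))
})

setMethod("show", "DiscretizationMap", function(object) {
  cat(sprintf(
    "DiscretizationMap: %d pairs in %d levels (k initial %d), discordance %d\n",
    length(object@pairKeys), length(object@levelWeights), object@kInitial,
    as.integer(object@objective)))
})

setMethod("show", "CoefficientVector", function(object) {
  cat(sprintf("CoefficientVector: %d columns, achieved PCC %.4f\n",
    length(object@a), object@achievedPcc))
})

setMethod("show", "InferredDAG", function(object) {
  ns <- sum(lengths(object@termGenes) > 1L)
  cat(sprintf(
    "InferredDAG (alpha %.3g, beta %.3g): %d terms (%d internal), %d links\n",
    object@alpha, object@beta, length(object@termGenes), ns,
    nrow(object@links)))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: %d aligned pairs, score cutoff %.4g\n",
    nrow(object@pairs), object@fdrThreshold))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld (seed %d): %d terms, %d genes, %d networks [%s]\n",
    object@seed, length(object@dag@termIds), length(object@annotations@direct),
    length(object@networks),
    paste(vapply(object@networks, function(n) n@name, character(1)),
      collapse = ", ")))
})
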