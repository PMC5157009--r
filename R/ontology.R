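#' Propagate direct annotations to all ancestral terms
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; this computes that closure. Alternative term ids are resolved
#' to their primary ids first; records pointing at unknown terms are skipped
#' with a warning (the count is kept on the returned object).
#'
#' @param dag an [OntologyDAG-class].
#' @param direct named list, gene -> character vector of directly annotated
#'   terms.
#' @return an [AnnotationSet-class].
#' @export
propagateAnnotations <- function(dag, direct) {
  anc <- .ancestorClosure(dag)
  nSkipped <- 0L
  clean <- lapply(direct, function(terms) {
    hit <- terms %in% names(dag@altIds)
    terms[hit] <- dag@altIds[terms[hit]]
    known <- terms %in% dag@termIds
    nSkipped <<- nSkipped + sum(!known)
    sort(unique(terms[known]))
  })
  clean <- clean[lengths(clean) > 0L]
  if (nSkipped > 0L)
    warning(nSkipped, " annotation record(s) referenced unknown terms ",
      "and were skipped")
  prop <- lapply(clean, function(terms)
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE)))))
  new("AnnotationSet", direct = clean, propagated = prop,
    nSkipped = nSkipped)
}

#' Term levels: shortest-path depth from the namespace root
#'
#' The root sits at level 1; every other term's level is one plus the length
#' of the shortest directed path to a root (the GO convention for term
#' depth). With several roots the minimum over roots is used.
#'
#' @param dag an [OntologyDAG-class].
#' @return named integer vector of levels.
#' @export
termLevels <- function(dag) {
  roots <- rootTerms(dag)
  if (length(roots) == 0L) stop("ontology has no root")
  g <- .dagGraph(dag)
  d <- igraph::distances(g, v = dag@termIds, to = roots, mode = "out")
  lv <- apply(d, 1L, min)
  setNames(as.integer(lv) + 1L, dag@termIds)
}

#' Select training sub-tree roots between two ontology levels
#'
#' Every term whose level (see [termLevels()]) lies in
#' \code{[minLevel, maxLevel]} identifies a training sub-tree: the term plus
#' all of its descendants. Requires a unique namespace root.
#'
#' @param dag an [OntologyDAG-class].
#' @param minLevel,maxLevel inclusive level bounds (defaults 2 and 5).
#' @return character vector of sub-tree root term ids (possibly empty).
#' @export
selectTrainingSubtrees <- function(dag, minLevel = 2L, maxLevel = 5L) {
  roots <- rootTerms(dag)
  if (length(roots) != 1L)
    stop("training sub-tree selection requires a unique namespace root")
  lv <- termLevels(dag)
  sort(names(lv)[lv >= minLevel & lv <= maxLevel])
}

#' Terms of the sub-tree rooted at a given term
#'
#' @param dag an [OntologyDAG-class].
#' @param root a term id in \code{dag}.
#' @return character vector: the root and all its descendants.
#' @export
trainingSubtreeTerms <- function(dag, root) {
  if (!root %in% dag@termIds) stop("unknown term: ", root)
  sort(.descendantClosure(dag, root)[[root]])
}

# annotations restricted to a term set: gene -> propagated terms within the
# set; genes with none are dropped
.restrictAnnotations <- function(annotations, terms) {
  res <- lapply(annotations@propagated, function(tt) intersect(tt, terms))
  res[lengths(res) > 0L]
}

#' Normalized simplified-Resnik similarity of two genes
#'
#' Within a training part, the similarity of genes \code{gA} and \code{gB}
#' is the information content of their most informative common ancestor
#' term, \code{-log(|G_LCA| / |G_tot|)}, divided by its maximum possible
#' value \code{-log(1 / |G_tot|)}. Here \code{|G_LCA|} is the number of
#' training genes annotated by that common ancestor and \code{|G_tot|} the
#' total number of training genes. Scores lie in [0, 1]; genes sharing no
#' common term score 0.
#'
#' @param trainingAnnotations named list, gene -> propagated terms within
#'   the training part (see the internals of [trainingPairSimilarities()]).
#' @param gA,gB two distinct annotated genes.
#' @return similarity in [0, 1].
#' @export
resnikSimilarity <- function(trainingAnnotations, gA, gB) {
  if (identical(gA, gB)) stop("genes must be distinct")
  if (!gA %in% names(trainingAnnotations) ||
      !gB %in% names(trainingAnnotations))
    stop("both genes must carry a training-part annotation")
  nTot <- length(trainingAnnotations)
  if (nTot < 2L) stop("need at least 2 training genes")
  counts <- table(unlist(trainingAnnotations, use.names = FALSE))
  common <- intersect(trainingAnnotations[[gA]], trainingAnnotations[[gB]])
  if (length(common) == 0L) return(0)
  nLca <- min(counts[common])
  log(nTot / nLca) / log(nTot)
}

#' Similarities of all training gene pairs under a training sub-tree
#'
#' Restricts the propagated annotations to the sub-tree rooted at
#' \code{trainingRoot}; the genes retaining at least one term are the
#' training genes. All unordered pairs of training genes are scored with the
#' normalized simplified-Resnik measure, and pairs scoring at least
#' \code{ts} are marked semantically similar.
#'
#' @param dag an [OntologyDAG-class].
#' @param trainingRoot the sub-tree root term (typically from
#'   [selectTrainingSubtrees()]).
#' @param annotations an [AnnotationSet-class] over \code{dag}.
#' @param ts similarity threshold for "semantically similar" (default 0.3).
#' @return a [TrainingSet-class].
#' @export
trainingPairSimilarities <- function(dag, trainingRoot, annotations,
                                     ts = 0.3) {
  subTerms <- trainingSubtreeTerms(dag, trainingRoot)
  restricted <- .restrictAnnotations(annotations, subTerms)
  genes <- sort(names(restricted))
  n <- length(genes)
  if (n < 2L) stop("fewer than 2 genes are annotated in the training part")

  # gene x term incidence over the training part
  termsU <- sort(unique(unlist(restricted, use.names = FALSE)))
  M <- matrix(FALSE, n, length(termsU), dimnames = list(genes, termsU))
  for (g in genes) M[g, restricted[[g]]] <- TRUE
  counts <- colSums(M)
  logTot <- log(n)

  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sim <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    common <- M[idx[r, 1L], ] & M[idx[r, 2L], ]
    sim[r] <- if (!any(common)) 0 else
      log(n / min(counts[common])) / logTot
  }
  pairs <- data.frame(geneA = genes[idx[, 1L]], geneB = genes[idx[, 2L]],
    similarity = sim, similar = sim >= ts, stringsAsFactors = FALSE)
  new("TrainingSet", pairs = pairs, genes = genes, ts = ts,
    trainingRoot = trainingRoot)
}

# gene sets of ontology terms: term -> genes whose propagated annotations
# contain it; terms annotating fewer than minGenes genes are dropped
#' Gene sets annotated by each ontology term
#'
#' @param dag an [OntologyDAG-class].
#' @param annotations an [AnnotationSet-class] over \code{dag}.
#' @param minGenes smallest gene-set size to keep (default 1).
#' @return named list, term -> character vector of genes.
#' @export
ontologyTermGenes <- function(dag, annotations, minGenes = 1L) {
  genes <- names(annotations@propagated)
  byTerm <- list()
  for (g in genes)
    for (t in annotations@propagated[[g]])
      byTerm[[t]] <- c(byTerm[[t]], g)
  byTerm <- lapply(byTerm, sort)
  byTerm <- byTerm[names(byTerm) %in% dag@termIds]
  byTerm[lengths(byTerm) >= minGenes]
}
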