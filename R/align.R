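#' Intrinsic similarity of two terms: Jaccard index of their gene sets
#'
#' @param genesA,genesB non-empty character vectors of genes.
#' @return |A intersect B| / |A union B|, in [0, 1].
#' @export
termSimilarity <- function(genesA, genesB) {
  if (length(genesA) == 0L || length(genesB) == 0L)
    stop("gene sets must be non-empty")
  length(intersect(genesA, genesB)) / length(union(genesA, genesB))
}

# gene sets + ancestor closure for either DAG flavour
.dagGeneSets <- function(dag, annotations = NULL, minGenes = 1L) {
  if (is(dag, "InferredDAG")) {
    sets <- dag@termGenes[lengths(dag@termGenes) >= minGenes]
    anc <- if (nrow(dag@links) > 0L) {
      g <- igraph::graph_from_data_frame(dag@links, directed = TRUE,
        vertices = data.frame(name = names(dag@termGenes)))
      res <- lapply(names(sets), function(t)
        setdiff(names(igraph::subcomponent(g, t, mode = "out")), t))
      setNames(res, names(sets))
    } else setNames(rep(list(character()), length(sets)), names(sets))
    list(sets = sets, ancestors = anc)
  } else if (is(dag, "OntologyDAG")) {
    if (is.null(annotations))
      stop("an OntologyDAG needs annotations to define term gene sets")
    sets <- ontologyTermGenes(dag, annotations, minGenes = minGenes)
    anc <- .ancestorClosure(dag)[names(sets)]
    list(sets = sets, ancestors = anc)
  } else stop("unsupported DAG class: ", class(dag))
}

# greedy one-to-one, no-crisscross matching over precomputed scores.
# scoreM: termX x termY matrix; ancX/ancY: term -> ancestor ids
.greedyMatch <- function(scoreM, ancX, ancY, sizesX, minScore = 0) {
  idx <- which(scoreM > minScore, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(termX = character(), termY = character(),
      score = numeric(), stringsAsFactors = FALSE))
  sc <- scoreM[idx]
  tx <- rownames(scoreM)[idx[, 1L]]
  ty <- colnames(scoreM)[idx[, 2L]]
  o <- order(-sc, sizesX[tx], tx, ty)
  tx <- tx[o]; ty <- ty[o]; sc <- sc[o]
  accX <- character(); accY <- character(); accS <- numeric()
  for (i in seq_along(sc)) {
    if (tx[i] %in% accX || ty[i] %in% accY) next
    # crisscross: an accepted pair whose x is an ancestor of tx while its
    # y is a descendant of ty, or vice versa
    cross <- FALSE
    for (j in seq_along(accX)) {
      xAnc <- accX[j] %in% ancX[[tx[i]]]   # accX[j] above tx[i]
      xDes <- tx[i] %in% ancX[[accX[j]]]   # accX[j] below tx[i]
      yAnc <- accY[j] %in% ancY[[ty[i]]]
      yDes <- ty[i] %in% ancY[[accY[j]]]
      if ((xAnc && yDes) || (xDes && yAnc)) { cross <- TRUE; break }
    }
    if (cross) next
    accX <- c(accX, tx[i]); accY <- c(accY, ty[i]); accS <- c(accS, sc[i])
  }
  data.frame(termX = accX, termY = accY, score = accS,
    stringsAsFactors = FALSE)
}

.scoreMatrix <- function(setsX, setsY, universe) {
  IX <- matrix(0, length(setsX), length(universe),
    dimnames = list(names(setsX), universe))
  for (t in names(setsX)) IX[t, intersect(setsX[[t]], universe)] <- 1
  IY <- matrix(0, length(setsY), length(universe),
    dimnames = list(names(setsY), universe))
  for (t in names(setsY)) IY[t, intersect(setsY[[t]], universe)] <- 1
  inter <- IX %*% t(IY)
  sx <- rowSums(IX); sy <- rowSums(IY)
  uni <- outer(sx, sy, "+") - inter
  sc <- inter / pmax(uni, 1)
  sc[uni == 0] <- 0
  sc
}

#' Align two ontology DAGs by intrinsic gene-set similarity
#'
#' Matches terms of \code{dagX} to terms of \code{dagY} greedily in
#' descending Jaccard similarity of their gene sets, under two
#' constraints: each term joins at most one pair, and no two accepted
#' pairs may crisscross (ancestor/descendant order inverted between the
#' two DAGs). Only pairs scoring above an FDR-calibrated cutoff are kept:
#' the null distribution of matched scores comes from \code{nPerm}
#' gene-label permutations of \code{dagX}'s gene sets, and the cutoff is
#' the smallest score at which (expected null pairs at or above it) /
#' (observed pairs at or above it) is at most \code{fdr}. Deterministic
#' given \code{seed}.
#'
#' @param dagX,dagY an [InferredDAG-class] or an [OntologyDAG-class].
#' @param annotationsX,annotationsY [AnnotationSet-class] objects, required
#'   for any [OntologyDAG-class] argument.
#' @param fdr false-discovery-rate cutoff (default 0.05).
#' @param nPerm number of label permutations for the null (default 100).
#' @param seed RNG seed.
#' @param minGenes drop terms with fewer genes than this before aligning
#'   (default 1; use 2 to ignore singleton leaves of inferred DAGs).
#' @param maxGeneFrac drop terms annotating more than this fraction of the
#'   shared gene universe (default 0.5). Near-universe terms carry almost
#'   no intrinsic information — a size-preserving label permutation
#'   reproduces them — so they would otherwise swamp the permutation null.
#' @return an [AlignmentResult-class] with \code{termX} from \code{dagX}.
#' @export
alignOntologies <- function(dagX, dagY, annotationsX = NULL,
                            annotationsY = NULL, fdr = 0.05,
                            nPerm = 100L, seed = 1L, minGenes = 1L,
                            maxGeneFrac = 0.5) {
  gx <- .dagGeneSets(dagX, annotationsX, minGenes)
  gy <- .dagGeneSets(dagY, annotationsY, minGenes)
  universe <- intersect(
    sort(unique(unlist(gx$sets, use.names = FALSE))),
    sort(unique(unlist(gy$sets, use.names = FALSE))))
  if (length(universe) > 0L && maxGeneFrac < 1) {
    cap <- maxGeneFrac * length(universe)
    gx$sets <- gx$sets[vapply(gx$sets, function(g)
      length(intersect(g, universe)), numeric(1)) <= cap]
    gy$sets <- gy$sets[vapply(gy$sets, function(g)
      length(intersect(g, universe)), numeric(1)) <= cap]
    if (length(gx$sets) == 0L || length(gy$sets) == 0L) {
      warning("no terms left after the size cap; empty alignment")
      return(new("AlignmentResult",
        pairs = data.frame(termX = character(), termY = character(),
          score = numeric(), stringsAsFactors = FALSE),
        fdrThreshold = Inf, nPerm = as.integer(nPerm)))
    }
  }
  if (length(universe) == 0L) {
    warning("no shared genes between the two DAGs; empty alignment")
    return(new("AlignmentResult",
      pairs = data.frame(termX = character(), termY = character(),
        score = numeric(), stringsAsFactors = FALSE),
      fdrThreshold = Inf, nPerm = as.integer(nPerm)))
  }
  sizesX <- setNames(lengths(gx$sets), names(gx$sets))
  scoreM <- .scoreMatrix(gx$sets, gy$sets, universe)
  observed <- .greedyMatch(scoreM, gx$ancestors, gy$ancestors, sizesX)

  if (nrow(observed) == 0L)
    return(new("AlignmentResult", pairs = observed, fdrThreshold = Inf,
      nPerm = as.integer(nPerm)))

  set.seed(seed)
  nullScores <- numeric()
  for (b in seq_len(nPerm)) {
    perm <- setNames(sample(universe), universe)
    setsP <- lapply(gx$sets, function(g) {
      g <- intersect(g, universe)
      unname(perm[g])
    })
    setsP <- setsP[lengths(setsP) > 0L]
    scP <- .scoreMatrix(setsP, gy$sets, universe)
    mP <- .greedyMatch(scP, gx$ancestors[names(setsP)], gy$ancestors,
      sizesX[names(setsP)])
    nullScores <- c(nullScores, mP$score)
  }

  cand <- sort(unique(observed$score))
  thr <- Inf
  for (c0 in cand) {
    nullAbove <- sum(nullScores >= c0) / nPerm
    obsAbove <- sum(observed$score >= c0)
    if (obsAbove > 0L && nullAbove / obsAbove <= fdr) { thr <- c0; break }
  }
  keep <- observed$score >= thr
  new("AlignmentResult", pairs = observed[keep, , drop = FALSE],
    fdrThreshold = thr, nPerm = as.integer(nPerm))
}

#' Inferred terms attributable to the training part
#'
#' Given the alignment of the all-genes inferred DAG against the DAG
#' inferred from the training genes alone, any aligned inferred term is
#' considered to derive directly from the training part and is excluded
#' from held-out evaluation.
#'
#' @param alignment an [AlignmentResult-class] whose \code{termX} side is
#'   the all-genes inferred DAG and \code{termY} side the training-only
#'   inferred DAG.
#' @return character vector of training-derived inferred term ids.
#' @export
flagTrainingDerived <- function(alignment) {
  unique(alignment@pairs$termX)
}

#' Held-out evaluation metrics of an inferred ontology
#'
#' \code{hit} counts aligned pairs whose reference term lies outside the
#' training part and whose inferred term is not training-derived.
#' Precision divides by the inferred terms net of training-derived ones,
#' recall by the reference terms outside the training part, and F is their
#' harmonic mean (0 when hit is 0).
#'
#' @param alignment alignment of the inferred DAG (termX) to the reference
#'   ontology (termY).
#' @param referenceTerms alignable terms of the reference ontology.
#' @param trainingTerms terms of the training sub-tree.
#' @param trainingDerived inferred terms attributable to the training part
#'   (from [flagTrainingDerived()]).
#' @param inferredTermCount number of candidate terms in the inferred DAG
#'   (its non-singleton terms).
#' @return an [EvalMetrics-class].
#' @export
evaluateAlignment <- function(alignment, referenceTerms, trainingTerms,
                              trainingDerived, inferredTermCount) {
  heldOut <- setdiff(referenceTerms, trainingTerms)
  if (length(heldOut) == 0L)
    stop("no reference terms outside the training part; recall undefined")
  p <- alignment@pairs
  hit <- sum(p$termY %in% heldOut & !(p$termX %in% trainingDerived))
  denomP <- inferredTermCount - length(trainingDerived)
  precision <- if (denomP > 0L) hit / denomP else 0
  recall <- hit / length(heldOut)
  f <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  new("EvalMetrics", hit = as.integer(hit),
    precision = min(precision, 1), recall = recall, fMeasure = f)
}

#' Write an alignment as a tab-separated table
#'
#' @param alignment an [AlignmentResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAlignment <- function(alignment, path) {
  write.table(alignment@pairs, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
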