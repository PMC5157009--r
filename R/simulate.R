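#' Generate a planted ontology with gene annotations
#'
#' Builds a rooted tree of the given depth and branching factor (terms
#' \code{L<level>_<index>}), optionally adds a fraction of extra parent
#' links (toward strictly shallower terms, so the graph stays acyclic and
#' some terms gain multiple parents), assigns genes round-robin to the
#' leaf terms and propagates the annotations upward.
#'
#' @param nGenes number of genes (>= number of leaves is typical).
#' @param depth tree depth; the root sits at level 1, leaves at level
#'   \code{depth} (>= 2).
#' @param branching children per internal term (>= 1).
#' @param extraParentFrac fraction of level >= 3 terms receiving a second
#'   parent (default 0.1).
#' @param seed RNG seed.
#' @return list with elements \code{dag} ([OntologyDAG-class]) and
#'   \code{annotations} ([AnnotationSet-class]).
#' @export
generateOntology <- function(nGenes, depth, branching,
                             extraParentFrac = 0.1, seed = 1L) {
  if (depth < 2L || branching < 1L || nGenes < 1L)
    stop("infeasible shape: need depth >= 2, branching >= 1, nGenes >= 1")
  set.seed(seed)
  levels <- lapply(seq_len(depth), function(l)
    sprintf("L%d_%02d", l, seq_len(branching^(l - 1L))))
  ids <- unlist(levels)
  links <- do.call(rbind, lapply(seq(2L, depth), function(l) {
    child <- levels[[l]]
    parent <- levels[[l - 1L]][ceiling(seq_along(child) / branching)]
    data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  }))
  if (extraParentFrac > 0 && depth >= 3L && branching > 1L) {
    for (l in seq(3L, depth)) {
      for (ch in levels[[l]]) {
        if (runif(1) < extraParentFrac) {
          cur <- links$parent[links$child == ch]
          cands <- setdiff(levels[[l - 1L]], cur)
          if (length(cands))
            links <- rbind(links, data.frame(child = ch,
              parent = cands[sample.int(length(cands), 1L)],
              stringsAsFactors = FALSE))
        }
      }
    }
  }
  dag <- new("OntologyDAG", termIds = ids,
    termNames = setNames(ids, ids), parentLinks = links,
    namespace = "synthetic", altIds = character())
  leaves <- levels[[depth]]
  genes <- sprintf("g%03d", seq_len(nGenes))
  leafOf <- rep(leaves, length.out = nGenes)
  direct <- setNames(as.list(leafOf), genes)
  ann <- propagateAnnotations(dag, direct)
  list(dag = dag, annotations = ann)
}

# similarity of all annotated gene pairs over the full ontology, as a
# named vector keyed by canonical pair
.groundTruthSimilarity <- function(dag, annotations) {
  root <- rootTerms(dag)
  if (length(root) != 1L) stop("planted ontology must have a unique root")
  ts <- trainingPairSimilarities(dag, root, annotations)
  p <- ts@pairs
  setNames(p$similarity, .pairKey(p$geneA, p$geneB))
}

.transformSignal <- function(s, transform) {
  switch(transform,
    identity = s,
    square = s^2,
    exp = (exp(3 * s) - 1) / (exp(3) - 1),
    saturating = s^0.25,
    stop("unknown transform: ", transform))
}

#' Generate heterogeneous noisy networks from a planted ontology
#'
#' Each network's base signal is the normalized ontological similarity of
#' every annotated gene pair. A per-network monotone transform (identity,
#' square, exponential rescale, or a binary threshold) deliberately gives
#' the networks different weight distributions; Gaussian noise with the
#' given standard deviation is added (for the binary transform, before
#' thresholding), weights are clipped to [0, 1], and a fraction of edges
#' is dropped uniformly at random to emulate incompleteness. Optionally a
#' network can be made informative only for the genes under one sub-tree:
#' outside pairs get their signal shuffled.
#'
#' @param dag the planted [OntologyDAG-class].
#' @param annotations its [AnnotationSet-class].
#' @param transforms character vector naming one transform per network,
#'   from \code{identity}, \code{square}, \code{exp}, \code{binary}.
#' @param noise per-network Gaussian noise standard deviation (recycled;
#'   default 0.3).
#' @param dropout fraction of edges dropped per network (default 0.3).
#' @param binaryCutoff similarity cutoff for the binary transform
#'   (default 0.3; edges form where noisy similarity >= cutoff).
#' @param informativeSubtree optional named list, network index ->
#'   character vector of sub-tree root terms: that network's signal is
#'   shuffled for pairs not fully inside the union of those sub-trees'
#'   genes, making the network informative only there (the
#'   differential-usefulness regime in which no single network covers the
#'   whole ontology).
#' @param seed RNG seed.
#' @return list of [WeightedNetwork-class] objects named by transform.
#' @export
generateNetworks <- function(dag, annotations,
                             transforms = c("identity", "square", "exp",
                               "binary"),
                             noise = 0.3, dropout = 0.3,
                             binaryCutoff = 0.3,
                             informativeSubtree = NULL, seed = 1L) {
  set.seed(seed)
  simAll <- .groundTruthSimilarity(dag, annotations)
  keys <- names(simAll)
  ab <- .splitKey(keys)
  genes <- sort(names(annotations@propagated))
  noise <- rep(noise, length.out = length(transforms))

  nets <- vector("list", length(transforms))
  netNames <- make.unique(transforms)
  for (i in seq_along(transforms)) {
    s <- unname(simAll)
    if (!is.null(informativeSubtree) &&
        !is.null(informativeSubtree[[as.character(i)]])) {
      roots <- informativeSubtree[[as.character(i)]]
      subGenes <- unique(unlist(lapply(roots, function(r)
        names(.restrictAnnotations(annotations,
          trainingSubtreeTerms(dag, r))))))
      inside <- ab[, 1L] %in% subGenes & ab[, 2L] %in% subGenes
      s[!inside] <- sample(s[!inside])
    }
    tr <- transforms[i]
    if (tr == "binary") {
      noisy <- s + rnorm(length(s), 0, noise[i])
      keep <- noisy >= binaryCutoff
      w <- rep(1, sum(keep))
      a <- ab[keep, 1L]; b <- ab[keep, 2L]
    } else {
      w <- .transformSignal(s, tr) + rnorm(length(s), 0, noise[i])
      w <- pmin(pmax(w, 0), 1)
      a <- ab[, 1L]; b <- ab[, 2L]
    }
    if (dropout > 0) {
      keep2 <- runif(length(w)) >= dropout
      a <- a[keep2]; b <- b[keep2]; w <- w[keep2]
    }
    nets[[i]] <- .newNetwork(a, b, w, genes, netNames[i])
  }
  names(nets) <- netNames
  nets
}

#' Generate a full synthetic world: ontology, annotations and networks
#'
#' The one-call generator behind the package's tests and examples. The
#' default shape (60 genes, depth-4 branching-3 tree, three networks with
#' identity/square transforms plus a binary one, noise 0.3, dropout 0.3)
#' is a desk-scale stand-in for the statistical structure the pipeline
#' assumes: several heterogeneous monotone views of one latent ontology.
#'
#' @param nGenes,depth,branching,extraParentFrac ontology shape; see
#'   [generateOntology()].
#' @param transforms,noise,dropout,binaryCutoff,informativeSubtree network
#'   generation; see [generateNetworks()].
#' @param seed RNG seed; regenerating with the same seed reproduces the
#'   world exactly.
#' @return a [SyntheticWorld-class].
#' @export
generateWorld <- function(nGenes = 60L, depth = 4L, branching = 3L,
                          extraParentFrac = 0.1,
                          transforms = c("identity", "square", "binary"),
                          noise = 0.3, dropout = 0.3, binaryCutoff = 0.3,
                          informativeSubtree = NULL, seed = 1L) {
  onto <- generateOntology(nGenes, depth, branching, extraParentFrac,
    seed = seed)
  nets <- generateNetworks(onto$dag, onto$annotations, transforms,
    noise = noise, dropout = dropout, binaryCutoff = binaryCutoff,
    informativeSubtree = informativeSubtree, seed = seed + 10000L)
  new("SyntheticWorld", dag = onto$dag, annotations = onto$annotations,
    networks = nets,
    params = list(nGenes = nGenes, depth = depth, branching = branching,
      extraParentFrac = extraParentFrac, transforms = transforms,
      noise = noise, dropout = dropout, binaryCutoff = binaryCutoff),
    seed = as.integer(seed))
}

#' Write a synthetic world to pipeline-readable files
#'
#' Emits the OBO ontology, a two-column annotation table and one
#' 3-column edge list per network into a directory, so synthetic fixtures
#' double as file-format round-trip tests.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"))
  writeObo(world@dag, paths$ontology)
  direct <- world@annotations@direct
  ann <- data.frame(gene = rep(names(direct), lengths(direct)),
    term = unlist(direct, use.names = FALSE), stringsAsFactors = FALSE)
  write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (nm in names(world@networks)) {
    p <- file.path(dir, paste0("network_", nm, ".tsv"))
    writeNetwork(world@networks[[nm]], p)
    paths[[paste0("network_", nm)]] <- p
  }
  invisible(paths)
}
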