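# shared pipeline internals -------------------------------------------------

# binary networks (all weights 1) are converted to weighted ones first
.prepareNetworks <- function(networks, tau = 1) {
  lapply(networks, function(net) {
    w <- net@edges$weight
    if (length(w) > 0L && all(w == 1)) diffusionKernel(net, tau = tau)
    else net
  })
}

# learned arm: filter, discretize, merge, fit, integrate
.learnedIntegration <- function(networks, training, params,
                                mergeMin = 10L, mergeMax = 20L,
                                nonNegative = TRUE) {
  filters <- list(); maps <- list(); kept <- list()
  for (i in seq_along(networks)) {
    fr <- tryCatch(learnThreshold(networks[[i]], training),
      error = function(e) NULL)
    if (is.null(fr)) next
    net <- filteredNetwork(fr)
    wmap <- .edgeWeightMap(net)
    p <- training@pairs
    keys <- .pairKey(p$geneA, p$geneB)
    tw <- wmap[keys[keys %in% names(wmap)]]
    if (length(tw) < 2L) next
    map <- searchDiscretization(setNames(as.numeric(tw), names(tw)),
      training, params)
    map <- mergeLevels(map, mergeMin, mergeMax)
    filters[[length(filters) + 1L]] <- fr
    maps[[length(maps) + 1L]] <- map
    kept[[length(kept) + 1L]] <- net
  }
  if (length(kept) == 0L)
    stop("no network retained any training edges; cannot integrate")
  design <- buildDesignMatrix(kept, maps, training)
  coef <- fitIntegration(design, training@pairs$similarity,
    nonNegative = nonNegative)
  integrated <- integrateNetworks(kept, maps, coef, rescale = TRUE)
  list(integrated = integrated, filters = filters, maps = maps,
    networks = kept, design = design, coef = coef)
}

# benchmark arm: per-network min-max scaling, unweighted summation
.summationIntegration <- function(networks, name = "summation") {
  scaled <- lapply(networks, .rescaleNetwork)
  acc <- new.env(parent = emptyenv())
  for (net in scaled) {
    e <- net@edges
    key <- paste(e$geneA, e$geneB, sep = "|")
    for (j in seq_along(key)) {
      prev <- acc[[key[j]]]
      acc[[key[j]]] <- if (is.null(prev)) e$weight[j]
        else prev + e$weight[j]
    }
  }
  keys <- ls(acc)
  genes <- sort(unique(unlist(lapply(networks, networkGenes))))
  if (length(keys) == 0L)
    return(new("WeightedNetwork", genes = genes, name = name))
  ab <- .splitKey(keys)
  w <- vapply(keys, function(k) acc[[k]], numeric(1))
  .rescaleNetwork(.newNetwork(ab[, 1L], ab[, 2L], unname(w), genes, name))
}

# infer O_G' and O_T' for each alpha, align, evaluate
.inferAndEvaluate <- function(integratedAll, integratedTrain, dag,
                              annotations, training, alphaGrid, beta,
                              fdr, nPerm, seed, minGenes = 2L,
                              maxGeneFrac = 0.5) {
  refSets <- ontologyTermGenes(dag, annotations, minGenes = minGenes)
  # the alignable reference terms: same size window the alignment uses
  nUniverse <- length(annotations@propagated)
  refSets <- refSets[lengths(refSets) <= maxGeneFrac * nUniverse]
  referenceTerms <- names(refSets)
  trainingTerms <- trainingSubtreeTerms(dag, training@trainingRoot)
  rows <- list()
  for (alpha in alphaGrid) {
    ogp <- inferDag(integratedAll, alpha = alpha, beta = beta)
    otp <- inferDag(integratedTrain, alpha = alpha, beta = beta)
    alignGT <- alignOntologies(ogp, otp, fdr = fdr, nPerm = nPerm,
      seed = seed, minGenes = minGenes)
    derived <- flagTrainingDerived(alignGT)
    alignGRef <- alignOntologies(ogp, dag, annotationsY = annotations,
      fdr = fdr, nPerm = nPerm, seed = seed + 1L, minGenes = minGenes)
    nInferred <- sum(lengths(ogp@termGenes) >= minGenes &
      lengths(ogp@termGenes) <= maxGeneFrac * nUniverse)
    m <- evaluateAlignment(alignGRef, referenceTerms, trainingTerms,
      derived, nInferred)
    rows[[length(rows) + 1L]] <- data.frame(alpha = alpha,
      inferredTerms = nInferred, trainingDerived = length(derived),
      hit = m@hit, precision = m@precision, recall = m@recall,
      f = m@fMeasure, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.writeRunOutputs <- function(outDir, label, metrics, arm = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write.table(metrics, file.path(outDir, paste0(label, "_metrics.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(arm)) {
    writeNetwork(arm$integrated,
      file.path(outDir, paste0(label, "_integrated.tsv")))
    writeCoefficientReport(arm$coef,
      file.path(outDir, paste0(label, "_coefficients.tsv")))
    names(arm$filters) <- vapply(arm$networks, function(n) n@name,
      character(1))
    writeFilterReport(arm$filters,
      file.path(outDir, paste0(label, "_filters.tsv")))
    for (i in seq_along(arm$maps))
      writeDiscretizationReport(arm$maps[[i]],
        file.path(outDir, sprintf("%s_discretization_%s.tsv", label,
          arm$networks[[i]]@name)))
  }
  invisible(NULL)
}

#' Run the full semi-supervised integration and inference pipeline
#'
#' End to end: pick (or accept) a training sub-tree, score the training
#' pairs, learn a filtering threshold per network, discretize each
#' filtered network against the training similarities, fit the linear
#' integration, infer a DAG from the integrated network for every alpha
#' in the grid, and evaluate on the held-out part of the ontology —
#' aligning the all-genes DAG both to a training-genes-only DAG (to flag
#' terms owed to the training part) and to the reference ontology.
#'
#' @param world a [SyntheticWorld-class]; or pass \code{dag},
#'   \code{annotations} and \code{networks} explicitly.
#' @param dag,annotations,networks explicit inputs (ignored when
#'   \code{world} is given).
#' @param trainingRoot training sub-tree root; default: the first root
#'   offered by [selectTrainingSubtrees()].
#' @param alphaGrid CliXO noise margins to sweep (integrated-weight units
#'   after [0, 1] rescaling).
#' @param beta missing-edge tolerance (default 0.5).
#' @param ts similarity threshold for "semantically similar" (default 0.3).
#' @param params discretization [SearchParams-class].
#' @param fdr,nPerm alignment FDR cutoff and permutation count.
#' @param tau diffusion time for binary input networks.
#' @param seed master seed for alignment permutations.
#' @param outDir optional directory for tab-separated reports.
#' @return list with \code{metrics} (one row per alpha), \code{meanF},
#'   \code{training}, \code{arm} (filters, maps, coefficients, integrated
#'   network) and \code{trainingRoot}.
#' @export
runPipeline <- function(world = NULL, dag = NULL, annotations = NULL,
                        networks = NULL, trainingRoot = NULL,
                        alphaGrid = c(0, 0.05, 0.1, 0.2, 0.3),
                        beta = 0.5, ts = 0.3, params = searchParams(),
                        fdr = 0.05, nPerm = 100L, tau = 1, seed = 1L,
                        outDir = NULL) {
  if (!is.null(world)) {
    dag <- world@dag; annotations <- world@annotations
    networks <- world@networks
  }
  if (is.null(trainingRoot))
    trainingRoot <- selectTrainingSubtrees(dag)[1L]
  nets <- .prepareNetworks(networks, tau = tau)
  training <- trainingPairSimilarities(dag, trainingRoot, annotations,
    ts = ts)

  armG <- .learnedIntegration(nets, training, params)
  trainNets <- lapply(nets, .restrictNetwork,
    genes = trainingGenes(training))
  armT <- tryCatch(.learnedIntegration(trainNets, training, params),
    error = function(e) NULL)
  integratedT <- if (is.null(armT))
    new("WeightedNetwork", genes = trainingGenes(training),
      name = "integrated") else armT$integrated

  metrics <- .inferAndEvaluate(armG$integrated, integratedT, dag,
    annotations, training, alphaGrid, beta, fdr, nPerm, seed)
  if (!is.null(outDir)) {
    .writeRunOutputs(outDir, "pipeline", metrics, armG)
    cfg <- data.frame(key = c("trainingRoot", "alphaGrid", "beta", "ts",
        "k", "maxIterations", "restarts", "fdr", "nPerm", "tau", "seed"),
      value = c(trainingRoot, paste(alphaGrid, collapse = ","), beta, ts,
        params@k, params@maxIterations, params@restarts, fdr, nPerm, tau,
        seed), stringsAsFactors = FALSE)
    write.table(cfg, file.path(outDir, "manifest.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  list(metrics = metrics, meanF = mean(metrics$f), training = training,
    arm = armG, trainingRoot = trainingRoot)
}

#' Run the equal-weight summation benchmark
#'
#' Identical protocol to [runPipeline()] but the learned filtering,
#' discretization and integration are replaced by per-network min-max
#' scaling and unweighted summation — the comparison arm that assumes all
#' networks matter equally.
#'
#' @inheritParams runPipeline
#' @return list with \code{metrics}, \code{meanF}, \code{training},
#'   \code{trainingRoot}.
#' @export
runBenchmarkSummation <- function(world = NULL, dag = NULL,
                                  annotations = NULL, networks = NULL,
                                  trainingRoot = NULL,
                                  alphaGrid = c(0, 0.05, 0.1, 0.2, 0.3),
                                  beta = 0.5, ts = 0.3, fdr = 0.05,
                                  nPerm = 100L, tau = 1, seed = 1L,
                                  outDir = NULL) {
  if (!is.null(world)) {
    dag <- world@dag; annotations <- world@annotations
    networks <- world@networks
  }
  if (is.null(trainingRoot))
    trainingRoot <- selectTrainingSubtrees(dag)[1L]
  nets <- .prepareNetworks(networks, tau = tau)
  training <- trainingPairSimilarities(dag, trainingRoot, annotations,
    ts = ts)
  integratedG <- .summationIntegration(nets)
  integratedT <- .summationIntegration(
    lapply(nets, .restrictNetwork, genes = trainingGenes(training)))
  metrics <- .inferAndEvaluate(integratedG, integratedT, dag, annotations,
    training, alphaGrid, beta, fdr, nPerm, seed)
  if (!is.null(outDir)) .writeRunOutputs(outDir, "summation", metrics)
  list(metrics = metrics, meanF = mean(metrics$f), training = training,
    trainingRoot = trainingRoot)
}

#' Run the pipeline on a single raw network
#'
#' The single-network arm: CliXO on one min-max-scaled network, evaluated
#' with the same held-out protocol.
#'
#' @inheritParams runPipeline
#' @param which index or name of the network to use.
#' @return list with \code{metrics}, \code{meanF}, \code{training},
#'   \code{trainingRoot}.
#' @export
runSingleNetwork <- function(world = NULL, dag = NULL, annotations = NULL,
                             networks = NULL, which = 1L,
                             trainingRoot = NULL,
                             alphaGrid = c(0, 0.05, 0.1, 0.2, 0.3),
                             beta = 0.5, ts = 0.3, fdr = 0.05,
                             nPerm = 100L, tau = 1, seed = 1L,
                             outDir = NULL) {
  if (!is.null(world)) {
    dag <- world@dag; annotations <- world@annotations
    networks <- world@networks
  }
  if (is.null(trainingRoot))
    trainingRoot <- selectTrainingSubtrees(dag)[1L]
  net <- .prepareNetworks(networks[which], tau = tau)[[1L]]
  training <- trainingPairSimilarities(dag, trainingRoot, annotations,
    ts = ts)
  integratedG <- .rescaleNetwork(net)
  integratedT <- .rescaleNetwork(
    .restrictNetwork(net, trainingGenes(training)))
  metrics <- .inferAndEvaluate(integratedG, integratedT, dag, annotations,
    training, alphaGrid, beta, fdr, nPerm, seed)
  if (!is.null(outDir))
    .writeRunOutputs(outDir, paste0("single_", net@name), metrics)
  list(metrics = metrics, meanF = mean(metrics$f), training = training,
    trainingRoot = trainingRoot)
}
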