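#' Learn a per-network edge-weight threshold from the training pairs
#'
#' Scans candidate thresholds \code{w} over the distinct edge weights of the
#' training-pair edges in descending order. At each \code{w} the fraction
#' \code{f(w)} of retained training edges (weight >= w) that are
#' semantically similar (similarity >= t_s) is computed; the threshold
#' \code{t_w} is the smallest scanned \code{w} with \code{f(w) >= 0.5}, so
#' as many relevant edges as possible are kept. If \code{f} fails to
#' increase for \code{patience} consecutive reductions before any
#' satisfying \code{w} is found, the scan stops and the value of \code{w}
#' in effect before those reductions is used as a fallback. The whole
#' network (training and left-out pairs alike) is then filtered to edges
#' with weight >= \code{t_w}; only training edges ever vote on the
#' threshold.
#'
#' @param net a [WeightedNetwork-class].
#' @param training a [TrainingSet-class].
#' @param patience number of consecutive non-increases of \code{f} that
#'   triggers the early stop (default 5).
#' @return a [FilterResult-class].
#' @export
learnThreshold <- function(net, training, patience = 5L) {
  wmap <- .edgeWeightMap(net)
  p <- training@pairs
  key <- .pairKey(p$geneA, p$geneB)
  hasEdge <- key %in% names(wmap)
  if (!any(hasEdge))
    stop("network has no edges between training genes; ",
      "threshold unlearnable")
  w <- unname(wmap[key[hasEdge]])
  similar <- p$similar[hasEdge]

  o <- order(w, decreasing = TRUE)
  w <- w[o]; similar <- similar[o]
  # f at each distinct weight, computed over all edges with weight >= it
  lastIdx <- cumsum(rle(w)$lengths)
  ws <- w[lastIdx]                      # distinct weights, descending
  f <- cumsum(similar)[lastIdx] / lastIdx

  tw <- NA_real_
  fallback <- FALSE
  noInc <- 0L
  for (i in seq_along(ws)) {
    if (i > 1L) {
      noInc <- if (f[i] > f[i - 1L]) 0L else noInc + 1L
    }
    if (f[i] >= 0.5) tw <- ws[i]        # keep descending: smallest wins
    if (noInc >= patience && is.na(tw)) {
      tw <- ws[i - patience]
      fallback <- TRUE
      break
    }
  }
  if (is.na(tw)) {                      # short scan, requirement never met
    tw <- ws[1L]
    fallback <- TRUE
  }

  fAt <- f[max(which(ws >= tw))]
  e <- net@edges
  kept <- e[e$weight >= tw, , drop = FALSE]
  rownames(kept) <- NULL
  new("FilterResult", tw = tw,
    network = new("WeightedNetwork", edges = kept, genes = net@genes,
      name = net@name),
    trainingFractionSimilar = fAt, fallbackUsed = fallback,
    nEdgesBefore = nrow(e), nEdgesAfter = nrow(kept))
}

#' Fraction of informative edges among a set of gene pairs
#'
#' Utility for the filtering diagnostics: among the network's edges whose
#' pairs belong to \code{pairKeys}, the fraction whose true ontological
#' similarity is at least \code{ts}.
#'
#' @param net a [WeightedNetwork-class].
#' @param similarity named numeric vector of similarities keyed by
#'   canonical "geneA|geneB" pair.
#' @param pairKeys which pairs to consider (e.g. the held-out pairs).
#' @param ts informativeness threshold (default 0.3).
#' @return fraction in [0, 1], or NA when no such edge exists.
#' @export
informativeFraction <- function(net, similarity, pairKeys, ts = 0.3) {
  e <- net@edges
  key <- paste(e$geneA, e$geneB, sep = "|")
  keep <- key %in% pairKeys & key %in% names(similarity)
  if (!any(keep)) return(NA_real_)
  mean(similarity[key[keep]] >= ts)
}

#' Write a per-network filter report
#'
#' @param results named list of [FilterResult-class] objects.
#' @param path output file (tab-separated).
#' @return the path, invisibly.
#' @export
writeFilterReport <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(network = nm, tw = r@tw, edgesBefore = r@nEdgesBefore,
      edgesAfter = r@nEdgesAfter,
      trainingFractionSimilar = r@trainingFractionSimilar,
      fallbackUsed = r@fallbackUsed, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
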