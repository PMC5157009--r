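#' Build the training design matrix over all networks' merged levels
#'
#' One row per training gene pair, one column per (network, merged level).
#' Entry (i, j) is the discretized edge weight of pair i if its edge in
#' column j's network falls in that level, else 0 — so per network each row
#' has at most one non-zero entry. Pairs with no edge in any network keep a
#' row of zeros (with a warning).
#'
#' @param networks list of filtered [WeightedNetwork-class] objects (raw
#'   weights; the maps supply the discretization).
#' @param maps list of [DiscretizationMap-class] objects, parallel to
#'   \code{networks}.
#' @param training the [TrainingSet-class] everything was learned with.
#' @return a [DesignMatrix-class].
#' @export
buildDesignMatrix <- function(networks, maps, training) {
  stopifnot(length(networks) == length(maps))
  p <- training@pairs
  keys <- .pairKey(p$geneA, p$geneB)
  netNames <- make.unique(vapply(seq_along(networks), function(i) {
    nm <- networks[[i]]@name
    if (is.na(nm) || nm == "network") paste0("net", i) else nm
  }, character(1)))

  cols <- do.call(rbind, lapply(seq_along(maps), function(i)
    data.frame(network = netNames[i],
      level = seq_along(maps[[i]]@levelWeights),
      weight = maps[[i]]@levelWeights, stringsAsFactors = FALSE)))
  M <- matrix(0, nrow = length(keys), ncol = nrow(cols))
  offset <- 0L
  for (i in seq_along(networks)) {
    wmap <- .edgeWeightMap(networks[[i]])
    hit <- keys %in% names(wmap)
    if (any(hit)) {
      w <- unname(wmap[keys[hit]])
      lvl <- .levelIndex(maps[[i]], w)
      M[cbind(which(hit), offset + lvl)] <- maps[[i]]@levelWeights[lvl]
    }
    offset <- offset + length(maps[[i]]@levelWeights)
  }
  if (any(rowSums(M != 0) == 0L))
    warning(sum(rowSums(M != 0) == 0L),
      " training pair(s) have no edge in any network; rows kept as zeros")
  new("DesignMatrix", M = M, columns = cols, pairKeys = keys)
}

#' Fit the linear integration maximizing correlation with similarity
#'
#' Finds the coefficient vector \code{a} maximizing the Pearson correlation
#' of \code{M a} with the training similarities \code{s}. With a single
#' response this canonical-correlation problem has the closed-form
#' least-squares solution on the centered columns; a small ridge
#' (\code{1e-8} on the diagonal) is used when the design is rank deficient.
#' The returned coefficients have unit Euclidean norm and carry the sign
#' that makes the achieved correlation non-negative.
#'
#' @param design a [DesignMatrix-class] (or plain numeric matrix).
#' @param s numeric vector of training similarities, one per design row.
#' @param nonNegative clamp coefficients to be non-negative via a projected
#'   coordinate solver (default FALSE; interpretability switch).
#' @return a [CoefficientVector-class].
#' @export
fitIntegration <- function(design, s, nonNegative = FALSE) {
  M <- if (is(design, "DesignMatrix")) design@M else as.matrix(design)
  cols <- if (is(design, "DesignMatrix")) design@columns else
    data.frame(network = "net", level = seq_len(ncol(M)),
      weight = NA_real_)
  if (nrow(M) < 2L) stop("need at least 2 training pairs")
  if (length(s) != nrow(M)) stop("s must have one entry per design row")
  if (stats::sd(s) == 0) stop("constant similarity vector; PCC undefined")
  if (all(M == 0)) stop("all-zero design matrix; PCC undefined")

  Mc <- scale(M, center = TRUE, scale = FALSE)
  sc <- s - mean(s)
  XtX <- crossprod(Mc)
  Xty <- crossprod(Mc, sc)
  a <- tryCatch(as.numeric(solve(XtX, Xty)),
    error = function(e)
      as.numeric(solve(XtX + diag(1e-8, ncol(M)), Xty)))
  if (nonNegative) {
    # projected cyclic coordinate descent on ||Mc a - sc||^2, a >= 0
    a <- pmax(a, 0)
    for (sweep in seq_len(200L)) {
      aOld <- a
      for (j in seq_len(ncol(Mc))) {
        r <- sc - Mc %*% a + Mc[, j] * a[j]
        denom <- XtX[j, j]
        a[j] <- if (denom > 0) max(0, sum(Mc[, j] * r) / denom) else 0
      }
      if (max(abs(a - aOld)) < 1e-10) break
    }
  }
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) stop("degenerate fit: zero coefficient vector")
  a <- a / nrm
  pcc <- stats::cor(as.numeric(M %*% a), s)
  if (is.na(pcc)) stop("combined score is constant; PCC undefined")
  if (pcc < 0) { a <- -a; pcc <- -pcc }
  new("CoefficientVector", a = a, achievedPcc = pcc, columns = cols)
}

#' Integrate discretized networks into a single weighted network
#'
#' Every gene pair with an edge in at least one network receives the
#' integrated weight \code{sum over networks of a[column of the pair's
#' level] * discretized weight} (networks without that edge contribute 0).
#' Pairs with no edge anywhere are absent. The result is min-max rescaled
#' to [0, 1] by default, the expected input scale of [inferDag()].
#'
#' @param networks list of filtered [WeightedNetwork-class] objects (raw
#'   weights), parallel to \code{maps}.
#' @param maps list of [DiscretizationMap-class] objects.
#' @param coef a [CoefficientVector-class] fitted on these networks' levels.
#' @param rescale min-max rescale the integrated weights to [0, 1]
#'   (default TRUE).
#' @param name label for the integrated network.
#' @return a [WeightedNetwork-class].
#' @export
integrateNetworks <- function(networks, maps, coef, rescale = TRUE,
                              name = "integrated") {
  stopifnot(length(networks) == length(maps))
  acc <- new.env(parent = emptyenv())
  offset <- 0L
  for (i in seq_along(networks)) {
    e <- networks[[i]]@edges
    if (nrow(e) > 0L) {
      lvl <- .levelIndex(maps[[i]], e$weight)
      contrib <- coef@a[offset + lvl] * maps[[i]]@levelWeights[lvl]
      key <- paste(e$geneA, e$geneB, sep = "|")
      for (j in seq_along(key)) {
        prev <- acc[[key[j]]]
        acc[[key[j]]] <- if (is.null(prev)) contrib[j] else prev + contrib[j]
      }
    }
    offset <- offset + length(maps[[i]]@levelWeights)
  }
  keys <- ls(acc)
  if (length(keys) == 0L) {
    genes <- sort(unique(unlist(lapply(networks, networkGenes))))
    return(new("WeightedNetwork", genes = genes, name = name))
  }
  w <- vapply(keys, function(k) acc[[k]], numeric(1))
  ab <- .splitKey(keys)
  genes <- sort(unique(unlist(lapply(networks, networkGenes))))
  net <- .newNetwork(ab[, 1L], ab[, 2L], unname(w), genes, name)
  if (rescale) .rescaleNetwork(net) else net
}

#' Write the integration coefficient report
#'
#' One row per design column (network, level, level weight, coefficient),
#' supporting inspection of each network's importance in the integration.
#'
#' @param coef a [CoefficientVector-class].
#' @param path output file (tab-separated).
#' @return the path, invisibly.
#' @export
writeCoefficientReport <- function(coef, path) {
  df <- cbind(coef@columns, coefficient = coef@a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# achieved PCC: %.6f", coef@achievedPcc), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
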