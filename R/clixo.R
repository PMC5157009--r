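#' Infer a term DAG from a weighted network by clique extraction
#'
#' Implements the clique-extracted-ontology (CliXO) construction as a
#' descending threshold sweep over the distinct edge weights. At threshold
#' t an edge is considered present when its weight is at least t - alpha
#' (alpha widens the band to absorb noise). Starting from one singleton
#' term per gene, the current top-level terms are repeatedly merged: a set
#' of top terms whose combined gene set forms a subgraph with at most a
#' fraction beta of its edges missing becomes a new term, parent of each
#' member, born at threshold t. Candidate sets are the maximal cliques
#' (Bron-Kerbosch with pivoting) of the graph connecting top-term pairs
#' that satisfy the density requirement, processed by descending gene-set
#' size then lexicographic gene set for determinism. A candidate whose
#' gene set duplicates an existing term is not created again; instead any
#' unabsorbed members become children of the existing term. The result is
#' a DAG in which every child's gene set is a strict subset of its
#' parents'.
#'
#' This is the algorithm as characterized in the CliXO literature at the
#' level of its defining ideas, not a bit-level port of the original
#' implementation: here beta is exactly the tolerated missing-edge
#' fraction and alpha exactly the edge-inclusion margin.
#'
#' @param net a [WeightedNetwork-class]; weights are treated as gene-gene
#'   similarities (typically the integrated network on a [0, 1] scale).
#' @param alpha noise margin added below each threshold (>= 0).
#' @param beta maximum tolerated fraction of missing edges in a new term's
#'   subgraph, in [0, 1] (default 0.5).
#' @param maxDegree guard for pathological inputs: genes with more network
#'   neighbours than this are excluded from merging (default Inf).
#' @return an [InferredDAG-class].
#' @export
inferDag <- function(net, alpha = 0, beta = 0.5, maxDegree = Inf) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  genes <- sort(net@genes)
  n <- length(genes)
  if (n == 0L) stop("empty network")

  W <- matrix(-Inf, n, n, dimnames = list(genes, genes))
  e <- net@edges
  if (nrow(e) > 0L) {
    ia <- match(e$geneA, genes); ib <- match(e$geneB, genes)
    W[cbind(ia, ib)] <- e$weight
    W[cbind(ib, ia)] <- e$weight
  }
  if (is.finite(maxDegree)) {
    deg <- rowSums(is.finite(W))
    if (any(deg > maxDegree))
      W[deg > maxDegree, ] <- W[, deg > maxDegree] <- -Inf
  }

  termGenes <- as.list(genes)
  names(termGenes) <- genes
  birth <- setNames(rep(NA_real_, n), genes)
  links <- list()
  geneSetKey <- setNames(names(termGenes),
    vapply(termGenes, paste, character(1), collapse = ","))
  top <- names(termGenes)
  nextId <- 1L

  thresholds <- sort(unique(e$weight), decreasing = TRUE)
  prevEdges <- -1L
  for (t in thresholds) {
    A <- W >= (t - alpha)
    nEdges <- sum(A) / 2L
    if (nEdges == prevEdges) next       # same graph as previous threshold
    prevEdges <- nEdges
    A0 <- A * 1; diag(A0) <- 0

    repeat {
      nt <- length(top)
      if (nt < 2L) break
      memb <- lapply(top, function(id) match(termGenes[[id]], genes))
      # pairwise union densities, vectorized for the common disjoint case:
      # S = term x gene incidence; E[i, j] = present edges between the two
      # gene sets; for disjoint sets present(union) = (Eii + Ejj) / 2 + Eij
      S <- matrix(0, nt, n)
      for (i in seq_len(nt)) S[i, memb[[i]]] <- 1
      E <- S %*% A0 %*% t(S)
      sz <- vapply(memb, length, integer(1))
      ov <- tcrossprod(S)                # gene-set overlap counts
      present <- (diag(E)[row(E)] + diag(E)[col(E)]) / 2 + E
      mU <- sz[row(E)] + sz[col(E)]
      possible <- mU * (mU - 1) / 2
      Hm <- present >= (1 - beta) * possible
      overlapping <- which(ov > 0 & row(ov) != col(ov) &
        upper.tri(ov), arr.ind = TRUE)
      for (r in seq_len(nrow(overlapping))) {
        i <- overlapping[r, 1L]; j <- overlapping[r, 2L]
        cc <- union(memb[[i]], memb[[j]])
        m <- length(cc)
        pres <- sum(A0[cc, cc]) / 2
        Hm[i, j] <- Hm[j, i] <- pres >= (1 - beta) * choose(m, 2)
      }
      diag(Hm) <- FALSE
      if (!any(Hm)) break
      H <- igraph::graph_from_adjacency_matrix(Hm, mode = "undirected")
      cls <- igraph::max_cliques(H, min = 2L)

      cand <- lapply(cls, function(cl) {
        ii <- as.integer(cl)
        gg <- sort(unique(unlist(memb[ii])))
        list(members = top[ii], genes = genes[gg])
      })
      sizes <- vapply(cand, function(x) length(x$genes), integer(1))
      keysc <- vapply(cand, function(x)
        paste(x$genes, collapse = ","), character(1))
      cand <- cand[order(-sizes, keysc)]

      changed <- FALSE
      absorbed <- character()
      for (cd in cand) {
        if (any(cd$members %in% absorbed)) next
        gg <- cd$genes
        m <- length(gg)
        ii <- match(gg, genes)
        pres <- sum(A0[ii, ii]) / 2
        if (pres < (1 - beta) * choose(m, 2)) next
        key <- paste(gg, collapse = ",")
        children <- cd$members[vapply(cd$members, function(id)
          length(termGenes[[id]]) < m, logical(1))]
        if (length(children) == 0L) next
        existing <- geneSetKey[key]
        if (!is.na(existing)) {
          # duplicate gene set: link unlinked children to the older term
          for (ch in setdiff(children, existing)) {
            already <- any(vapply(links, function(l)
              l[1L] == ch && l[2L] == existing, logical(1)))
            if (!already) {
              links[[length(links) + 1L]] <- c(ch, existing)
              absorbed <- c(absorbed, ch)
              changed <- TRUE
            }
          }
          next
        }
        id <- sprintf("C%04d", nextId)
        nextId <- nextId + 1L
        termGenes[[id]] <- gg
        birth[id] <- t
        geneSetKey[key] <- id
        for (ch in children)
          links[[length(links) + 1L]] <- c(ch, id)
        absorbed <- c(absorbed, children)
        top <- c(top, id)
        changed <- TRUE
      }
      top <- setdiff(top, absorbed)
      if (!changed) break
    }
  }

  linkDf <- if (length(links))
    unique(data.frame(child = vapply(links, `[`, character(1), 1L),
      parent = vapply(links, `[`, character(1), 2L),
      stringsAsFactors = FALSE))
  else data.frame(child = character(), parent = character(),
    stringsAsFactors = FALSE)
  rownames(linkDf) <- NULL
  new("InferredDAG", termGenes = termGenes, links = linkDf,
    birth = birth, alpha = alpha, beta = beta)
}

#' Export an inferred DAG as tab-separated tables
#'
#' Writes a 3-column term-relation table (child, parent, relation) to
#' \code{path} and a term-to-gene annotation table alongside it
#' (\code{<path>.genes}, columns term and gene). [readDag()] reverses it.
#'
#' @param dag an [InferredDAG-class].
#' @param path output file for the relation table.
#' @return the path, invisibly.
#' @export
exportDag <- function(dag, path) {
  rel <- cbind(dag@links, relation = rep("is_a", nrow(dag@links)))
  write.table(rbind(c("child", "parent", "relation")), path, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (nrow(rel) > 0L)
    write.table(rel, path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE, append = TRUE)
  ann <- do.call(rbind, lapply(names(dag@termGenes), function(id)
    data.frame(term = id, gene = dag@termGenes[[id]],
      birth = dag@birth[[id]], stringsAsFactors = FALSE)))
  gpath <- paste0(path, ".genes")
  write.table(rbind(c("term", "gene", "birth")), gpath, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(ann))
    write.table(ann, gpath, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read back an inferred DAG written by exportDag
#'
#' @param path the relation-table file (expects \code{<path>.genes} next to
#'   it).
#' @param alpha,beta parameter values to record on the object (not stored
#'   in the files).
#' @return an [InferredDAG-class].
#' @export
readDag <- function(path, alpha = NA_real_, beta = NA_real_) {
  rel <- read.delim(path, stringsAsFactors = FALSE)
  ann <- read.delim(paste0(path, ".genes"), stringsAsFactors = FALSE)
  termGenes <- lapply(split(ann$gene, ann$term), sort)
  birth <- vapply(split(ann$birth, ann$term), `[`, numeric(1), 1L)
  links <- if (nrow(rel) > 0L)
    data.frame(child = rel$child, parent = rel$parent,
      stringsAsFactors = FALSE)
  else data.frame(child = character(), parent = character(),
    stringsAsFactors = FALSE)
  new("InferredDAG", termGenes = termGenes, links = links,
    birth = birth[names(termGenes)], alpha = alpha, beta = beta)
}
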