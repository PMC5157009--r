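#' Read a weighted edge list into a WeightedNetwork
#'
#' Expects tab-separated rows \code{geneA geneB weight} (gzip transparent;
#' a header line is auto-detected from a non-numeric weight field in row 1).
#' Edges touching genes outside \code{geneUniverse} are dropped with a
#' message, self-loops are dropped, and duplicate unordered pairs collapse
#' to their maximum weight. Files with extra columns can be read by naming
#' the relevant ones in \code{columns}; an optional interaction-type filter
#' keeps only rows whose type column matches.
#'
#' @param path edge-list file.
#' @param geneUniverse optional character vector restricting nodes (e.g.
#'   the annotated genes); \code{NULL} keeps everything.
#' @param name label for the network (defaults to the file name).
#' @param columns integer vector \code{c(geneA, geneB, weight)} giving
#'   column positions; \code{weight = NA} reads a binary network (all
#'   weights 1).
#' @param typeColumn,keepTypes optional interaction-type filter: column
#'   position and the values to keep.
#' @return a [WeightedNetwork-class].
#' @export
readNetwork <- function(path, geneUniverse = NULL,
                        name = basename(path),
                        columns = c(1L, 2L, 3L),
                        typeColumn = NULL, keepTypes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(new("WeightedNetwork",
      genes = if (is.null(geneUniverse)) character() else geneUniverse,
      name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hasWeight <- !is.na(columns[3L])
  if (hasWeight && length(fields) > 1L) {
    # a header row: non-numeric weight in row 1 but numeric in row 2
    w1 <- suppressWarnings(as.numeric(fields[[1L]][columns[3L]]))
    w2 <- suppressWarnings(as.numeric(fields[[2L]][columns[3L]]))
    if (is.na(w1) && !is.na(w2)) { fields <- fields[-1L]; lines <- lines[-1L] }
  }
  a <- vapply(fields, `[`, character(1), columns[1L])
  b <- vapply(fields, `[`, character(1), columns[2L])
  if (!is.null(typeColumn)) {
    keep <- vapply(fields, `[`, character(1), typeColumn) %in% keepTypes
    a <- a[keep]; b <- b[keep]; fields <- fields[keep]; lines <- lines[keep]
  }
  if (hasWeight) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1),
      columns[3L])))
    if (anyNA(w))
      stop("non-numeric weight at line ", which(is.na(w))[1L], " of ", path)
  } else {
    w <- rep(1, length(a))
  }

  keep <- a != b
  if (!is.null(geneUniverse)) {
    inUniv <- a %in% geneUniverse & b %in% geneUniverse
    nDropped <- sum(keep & !inUniv)
    if (nDropped > 0L)
      message(nDropped, " edge(s) dropped: endpoint outside gene universe")
    keep <- keep & inUniv
  }
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  key <- .pairKey(a, b)
  w <- tapply(w, key, max)
  ab <- .splitKey(names(w))
  genes <- if (is.null(geneUniverse)) sort(unique(c(ab[, 1L], ab[, 2L])))
    else sort(unique(geneUniverse))
  .newNetwork(ab[, 1L], ab[, 2L], as.numeric(w), genes, name)
}

#' Write a network as a 3-column tab-separated edge list
#'
#' @param net a [WeightedNetwork-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, path) {
  write.table(net@edges, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Diffusion-kernel weighting of a binary network
#'
#' Converts a binary interaction network into a weighted one via the graph
#' diffusion kernel \code{expm(-tau * L)} with the symmetric normalized
#' Laplacian \code{L}. Within each connected component every node pair gets
#' the kernel value; all off-diagonal values are then divided by the global
#' maximum so weights land in (0, 1], larger for more directly or
#' indirectly connected pairs. Pairs in different components get no edge,
#' and entries below \code{minWeight} are dropped to keep the result
#' sparse.
#'
#' @param net a [WeightedNetwork-class] whose weights are all 1.
#' @param tau diffusion time (> 0, default 1).
#' @param minWeight sparsification cutoff (default 1e-6).
#' @return a [WeightedNetwork-class] with weights in (0, 1].
#' @export
diffusionKernel <- function(net, tau = 1, minWeight = 1e-6) {
  if (tau <= 0) stop("tau must be positive")
  e <- net@edges
  if (nrow(e) > 0L && any(e$weight != 1))
    stop("diffusionKernel expects a binary network (all weights 1)")
  if (nrow(e) == 0L)
    return(new("WeightedNetwork", genes = net@genes,
      name = paste0(net@name, "_kernel")))

  g <- igraph::graph_from_data_frame(e[, c("geneA", "geneB")],
    directed = FALSE)
  comp <- igraph::components(g)
  outA <- character(); outB <- character(); outW <- numeric()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    deg <- Matrix::rowSums(A)
    dinv <- 1 / sqrt(deg)
    L <- Matrix::Diagonal(length(members)) -
      Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
    K <- as.matrix(Matrix::expm(-tau * L))
    nm <- igraph::V(sub)$name
    iu <- which(upper.tri(K), arr.ind = TRUE)
    outA <- c(outA, nm[iu[, 1L]])
    outB <- c(outB, nm[iu[, 2L]])
    outW <- c(outW, K[iu])
  }
  if (length(outW) == 0L)
    return(new("WeightedNetwork", genes = net@genes,
      name = paste0(net@name, "_kernel")))
  outW <- outW / max(outW)
  keep <- outW >= minWeight
  .newNetwork(outA[keep], outB[keep], outW[keep], net@genes,
    paste0(net@name, "_kernel"))
}

# fast lookup: named numeric vector of weights keyed by "geneA|geneB"
.edgeWeightMap <- function(net) {
  e <- net@edges
  setNames(e$weight, paste(e$geneA, e$geneB, sep = "|"))
}

# induced subnetwork on a gene subset
.restrictNetwork <- function(net, genes) {
  e <- net@edges
  keep <- e$geneA %in% genes & e$geneB %in% genes
  new("WeightedNetwork", edges = e[keep, , drop = FALSE],
    genes = intersect(net@genes, genes), name = net@name)
}

# min-max rescale of edge weights to [0, 1]
.rescaleNetwork <- function(net) {
  w <- net@edges$weight
  if (length(w) == 0L) return(net)
  rng <- range(w)
  e <- net@edges
  e$weight <- if (diff(rng) == 0) rep(1, length(w))
    else (w - rng[1L]) / diff(rng)
  new("WeightedNetwork", edges = e, genes = net@genes, name = net@name)
}
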