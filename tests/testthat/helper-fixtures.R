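# in-code fixtures shared across test files

# write a small OBO file and return its path
makeOboFile <- function(stanzas) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}

# a 3-term chain A <- B <- C in one namespace
chainObo <- function() {
  makeOboFile(c(
    "[Term]", "id: A", "name: root", "namespace: toy", "",
    "[Term]", "id: B", "name: mid", "namespace: toy", "is_a: A", "",
    "[Term]", "id: C", "name: leaf", "namespace: toy", "is_a: B"))
}

# diamond: A <- {B, C} <- D
diamondObo <- function() {
  makeOboFile(c(
    "[Term]", "id: A", "namespace: toy", "",
    "[Term]", "id: B", "namespace: toy", "is_a: A", "",
    "[Term]", "id: C", "namespace: toy", "is_a: A", "",
    "[Term]", "id: D", "namespace: toy", "is_a: B",
    "relationship: part_of C"))
}

# OntologyDAG built directly (no file round trip)
makeDag <- function(links, ids = NULL, namespace = "toy") {
  ids <- if (is.null(ids)) unique(c(links$child, links$parent)) else ids
  new("OntologyDAG", termIds = ids, termNames = setNames(ids, ids),
    parentLinks = links, namespace = namespace, altIds = character())
}

# the 6-gene two-branch fixture used for closed-form Resnik checks:
# root R; branches X (genes g1 g2 g3 via term X) and Y (g4 g5 g6 via Y);
# deeper term XZ under X annotating g1 g2
sixGeneWorld <- function() {
  dag <- makeDag(data.frame(
    child = c("X", "Y", "XZ"), parent = c("R", "R", "X"),
    stringsAsFactors = FALSE))
  direct <- list(g1 = "XZ", g2 = "XZ", g3 = "X", g4 = "Y", g5 = "Y",
    g6 = "Y")
  ann <- propagateAnnotations(dag, direct)
  list(dag = dag, annotations = ann)
}

makeNetwork <- function(a, b, w, genes = NULL, name = "net") {
  genes <- if (is.null(genes)) sort(unique(c(a, b))) else genes
  ontonet:::.newNetwork(a, b, w, genes, name)
}

# training set built directly from explicit pair similarities
makeTraining <- function(geneA, geneB, sim, ts = 0.3, root = "R") {
  genes <- sort(unique(c(geneA, geneB)))
  new("TrainingSet", pairs = data.frame(geneA = pmin(geneA, geneB),
    geneB = pmax(geneA, geneB), similarity = sim, similar = sim >= ts,
    stringsAsFactors = FALSE), genes = genes, ts = ts, trainingRoot = root)
}

# exhaustive-enumeration oracle for the discretization optimum: minimal
# discordance over all order-preserving partitions of the weight groups
# into at most k levels
bruteForceDiscretization <- function(weights, sims, k) {
  o <- order(weights)
  w <- weights[o]; s <- sims[o]
  grp <- cumsum(c(TRUE, diff(w) > 0))
  m <- max(grp)
  best <- Inf
  cutSets <- list(integer(0))
  if (m > 1L) {
    for (nc in seq_len(min(k, m) - 1L))
      cutSets <- c(cutSets, utils::combn(m - 1L, nc, simplify = FALSE))
  }
  for (cuts in cutSets) {
    lev <- rep(seq_len(length(cuts) + 1L),
      diff(c(0L, cuts, m)))[grp]
    obj <- ontonet:::.discordanceVec(lev, s)
    if (obj < best) best <- obj
  }
  best
}

# a small InferredDAG built by hand (singleton leaves added automatically)
makeInferred <- function(sets, links = NULL) {
  singles <- unique(unlist(sets, use.names = FALSE))
  tg <- c(sets, setNames(as.list(singles), singles))
  lk <- if (is.null(links))
    data.frame(child = character(), parent = character(),
      stringsAsFactors = FALSE) else links
  new("InferredDAG", termGenes = tg, links = lk,
    birth = setNames(rep(NA_real_, length(tg)), names(tg)),
    alpha = 0, beta = 0.5)
}

# random gene-set DAG with parent links wherever sets nest
randomInferred <- function(nGenes, nTerms, seed) {
  set.seed(seed)
  genes <- paste0("g", seq_len(nGenes))
  sets <- list()
  for (i in seq_len(nTerms))
    sets[[paste0("T", i)]] <- sort(sample(genes,
      sample(2:max(3, nGenes %/% 3), 1)))
  links <- list()
  nm <- names(sets)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[i]]) < length(sets[[j]]))
      links[[length(links) + 1L]] <- c(nm[i], nm[j])
  }
  lk <- if (length(links)) unique(data.frame(
    child = vapply(links, `[`, character(1), 1),
    parent = vapply(links, `[`, character(1), 2),
    stringsAsFactors = FALSE)) else NULL
  makeInferred(sets, lk)
}
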