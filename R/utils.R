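# internal helpers shared across modules

# canonical unordered-pair key
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

.splitKey <- function(key) {
  do.call(rbind, strsplit(key, "|", fixed = TRUE))
}

# igraph over the child -> parent links of an OntologyDAG; vertices cover
# all terms, including isolated ones
.dagGraph <- function(dag) {
  igraph::graph_from_data_frame(dag@parentLinks, directed = TRUE,
    vertices = data.frame(name = dag@termIds, stringsAsFactors = FALSE))
}

# named list: term -> all ancestors (excluding the term itself)
.ancestorClosure <- function(dag) {
  g <- .dagGraph(dag)
  res <- lapply(dag@termIds, function(t)
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t))
  names(res) <- dag@termIds
  res
}

# named list: term -> the term plus all its descendants
.descendantClosure <- function(dag, terms = dag@termIds) {
  g <- .dagGraph(dag)
  res <- lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "in")))
  names(res) <- terms
  res
}

.newNetwork <- function(geneA, geneB, weight, genes, name = "network") {
  a <- pmin(geneA, geneB)
  b <- pmax(geneA, geneB)
  new("WeightedNetwork",
    edges = data.frame(geneA = a, geneB = b, weight = weight,
      stringsAsFactors = FALSE),
    genes = genes, name = name)
}
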