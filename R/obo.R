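#' Load one namespace of an OBO ontology file
#'
#' Parses the flat-file OBO subset sufficient for GO-style ontologies:
#' \code{[Term]} stanzas with \code{id}, \code{name}, \code{namespace},
#' \code{alt_id}, \code{is_a}, \code{relationship: part_of} and
#' \code{is_obsolete} tags. Obsolete terms are dropped; \code{is_a} and
#' \code{part_of} links are collapsed into a single parent relation; links
#' whose parent falls outside the requested namespace are dropped.
#'
#' @param path path to the OBO file (gzip transparent).
#' @param namespace which namespace to extract. When the file holds a single
#'   namespace (or only a \code{default-namespace} header) it may be omitted.
#' @return an [OntologyDAG-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: T:1", "name: root", "namespace: toy", "",
#'   "[Term]", "id: T:2", "name: mid", "namespace: toy", "is_a: T:1", "",
#'   "[Term]", "id: T:3", "name: leaf", "namespace: toy", "is_a: T:2"), obo)
#' dag <- loadOntology(obo, "toy")
#' rootTerms(dag)
#' @export
loadOntology <- function(path, namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  defaultNs <- sub("^default-namespace: *", "",
    grep("^default-namespace:", lines, value = TRUE))
  if (length(defaultNs) == 0L) defaultNs <- NA_character_

  starts <- grep("^\\[Term\\] *$", lines)
  anyStanza <- grep("^\\[", lines)
  terms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    from <- starts[i] + 1L
    nxt <- anyStanza[anyStanza > starts[i]]
    to <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[seq(from, to)]
    block <- block[nzchar(block)]
    tag <- sub(":.*$", "", block)
    val <- sub("^[^:]+: *", "", block)
    val <- sub(" *!.*$", "", val)  # strip trailing comments
    rel <- val[tag == "relationship"]
    partOf <- sub("^part_of +", "", rel[grepl("^part_of +", rel)])
    terms[[i]] <- list(
      id = val[tag == "id"][1],
      name = if (any(tag == "name")) val[tag == "name"][1] else NA_character_,
      namespace = if (any(tag == "namespace")) val[tag == "namespace"][1]
        else defaultNs,
      parents = c(val[tag == "is_a"], partOf),
      altIds = val[tag == "alt_id"],
      obsolete = any(tag == "is_obsolete" & val == "true"))
  }
  terms <- terms[!vapply(terms, function(t) is.na(t$id), logical(1))]
  if (length(terms) == 0L) stop("no [Term] stanzas found in ", path)

  nss <- unique(vapply(terms, function(t) t$namespace, character(1)))
  nss <- nss[!is.na(nss)]
  if (is.null(namespace)) {
    if (length(nss) > 1L)
      stop("file holds several namespaces (", paste(nss, collapse = ", "),
        "); pick one")
    namespace <- if (length(nss)) nss else NA_character_
  } else if (length(nss) && !namespace %in% nss) {
    stop("unknown namespace '", namespace, "'; available: ",
      paste(nss, collapse = ", "))
  }

  keep <- vapply(terms, function(t)
    !t$obsolete && (is.na(namespace) || identical(t$namespace, namespace)),
    logical(1))
  terms <- terms[keep]
  if (length(terms) == 0L)
    stop("namespace '", namespace, "' has no non-obsolete terms")

  ids <- vapply(terms, function(t) t$id, character(1))
  nms <- vapply(terms, function(t) t$name, character(1))
  links <- do.call(rbind, lapply(terms, function(t)
    if (length(t$parents))
      data.frame(child = t$id, parent = t$parents, stringsAsFactors = FALSE)
    else NULL))
  if (is.null(links))
    links <- data.frame(child = character(), parent = character(),
      stringsAsFactors = FALSE)
  links <- links[links$parent %in% ids, , drop = FALSE]
  links <- unique(links)
  rownames(links) <- NULL

  altPairs <- do.call(rbind, lapply(terms, function(t)
    if (length(t$altIds)) cbind(t$altIds, t$id) else NULL))
  altIds <- if (is.null(altPairs)) character() else
    setNames(altPairs[, 2], altPairs[, 1])

  if (nrow(links) > 0L) {
    g <- igraph::graph_from_data_frame(links, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("ontology links form a cycle; input rejected")
  }

  new("OntologyDAG", termIds = ids, termNames = setNames(nms, ids),
    parentLinks = links, namespace = namespace, altIds = altIds)
}

#' Write an ontology DAG in OBO flat-file format
#'
#' Emits the same subset [loadOntology()] reads, so synthetic ontologies
#' round-trip through files.
#'
#' @param dag an [OntologyDAG-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  byChild <- split(dag@parentLinks$parent, dag@parentLinks$child)
  for (id in dag@termIds) {
    nm <- dag@termNames[[id]]
    stanza <- c("[Term]", paste0("id: ", id),
      if (!is.na(nm)) paste0("name: ", nm),
      if (!is.na(dag@namespace)) paste0("namespace: ", dag@namespace),
      paste0("is_a: ", byChild[[id]]), "")
    writeLines(stanza, con)
  }
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Accepts either a plain two-column tab-separated file (gene, term) or a
#' GAF-style file (15+ columns; columns 2, 5 and 7 are used as gene id,
#' term id and evidence code). Comment lines starting with \code{!} are
#' skipped. Evidence filtering is a pass-through option; the default keeps
#' everything.
#'
#' @param path annotation file.
#' @param evidence optional character vector of evidence codes to keep
#'   (GAF input only).
#' @return named list, gene -> character vector of directly annotated terms.
#' @export
readAnnotations <- function(path, evidence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (all(ncols >= 15L)) {
    gene <- vapply(fields, `[`, character(1), 2L)
    term <- vapply(fields, `[`, character(1), 5L)
    ev <- vapply(fields, `[`, character(1), 7L)
    if (!is.null(evidence)) {
      keep <- ev %in% evidence
      gene <- gene[keep]; term <- term[keep]
    }
  } else {
    gene <- vapply(fields, `[`, character(1), 1L)
    term <- vapply(fields, `[`, character(1), 2L)
  }
  tapply(term, gene, function(x) sort(unique(x)), simplify = FALSE)[]
}
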