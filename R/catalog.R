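#' Construct a catalog of named gene sets over a shared universe
#'
#' A catalog holds the gene categories (TF, RBP, lncRNA, cancer-related,
#' mutation classes), tissue-specific sets keyed to cohorts, and pathway
#' sets used across the pipeline.  Gene identity is the bare, case-sensitive
#' symbol string; no alias resolution is attempted.
#'
#' @param sets Named list of character vectors; duplicate members within a
#'   set are collapsed.
#' @param kind Set kind(s): `"category"`, `"tissue"` or `"pathway"`.  Either
#'   one value recycled to all sets or a vector named like `sets`.
#' @param universe Optional character vector; defaults to the union of all
#'   set members.  Every member of every set must be in the universe.
#' @param tissue_to_cohort Named character vector mapping tissue set names to
#'   cohort ids; names must be tissue-kind sets.
#'
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(sets = list(), kind = "category", universe = NULL,
                         tissue_to_cohort = character()) {
  if (length(sets) > 0 &&
      (is.null(names(sets)) || any(names(sets) == ""))) {
    abort_format("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) {
    abort_format(sprintf("duplicate set name(s): %s",
      paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  bad_kind <- setdiff(unique(kind), c("category", "tissue", "pathway"))
  if (length(bad_kind) > 0) {
    abort_format(sprintf("unknown set kind: %s", paste(bad_kind, collapse = ", ")))
  }
  if (length(kind) == 1) {
    kind <- setNames(rep(kind, length(sets)), names(sets))
  } else {
    miss <- setdiff(names(sets), names(kind))
    if (length(miss) > 0) {
      abort_format(sprintf("no kind given for set(s): %s",
                           paste(miss, collapse = ", ")))
    }
    kind <- kind[names(sets)]
  }
  universe <- unique(as.character(universe %||% unlist(sets, use.names = FALSE)))
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside) > 0) {
    abort_format(sprintf("set member(s) outside the universe: %s",
                         paste(head(outside, 5), collapse = ", ")))
  }
  tissue_sets <- names(sets)[kind == "tissue"]
  stray <- setdiff(names(tissue_to_cohort), tissue_sets)
  if (length(stray) > 0) {
    abort_format(sprintf(
      "tissue_to_cohort refers to non-tissue set(s): %s",
      paste(stray, collapse = ", ")))
  }
  structure(
    list(universe = universe, sets = sets, set_kind = kind,
         tissue_to_cohort = tissue_to_cohort),
    class = "gene_catalog"
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes; %d sets (%d category, %d tissue, %d pathway)\n",
              length(x$universe), length(x$sets),
              sum(x$set_kind == "category"), sum(x$set_kind == "tissue"),
              sum(x$set_kind == "pathway")))
  invisible(x)
}

#' Combine gene-catalog fragments
#'
#' Universes are unioned; set names must not collide across fragments.
#'
#' @param ... `gene_catalog` objects.
#' @return A single [gene_catalog()].
#' @export
catalog_bind <- function(...) {
  frags <- list(...)
  stopifnot(all(vapply(frags, inherits, logical(1), "gene_catalog")))
  gene_catalog(
    sets = do.call(c, lapply(frags, `[[`, "sets")),
    kind = do.call(c, lapply(frags, `[[`, "set_kind")),
    universe = unique(unlist(lapply(frags, `[[`, "universe"))),
    tissue_to_cohort = do.call(c, lapply(frags, `[[`, "tissue_to_cohort"))
  )
}

#' Names of catalog sets of a given kind
#' @param catalog A [gene_catalog()].
#' @param kind `"category"`, `"tissue"` or `"pathway"`.
#' @return Character vector of set names.
#' @export
sets_of_kind <- function(catalog, kind) {
  names(catalog$sets)[catalog$set_kind == kind]
}

#' Attach a tissue-set to cohort mapping to a catalog
#' @inheritParams sets_of_kind
#' @param map Named character vector, tissue set name -> cohort id.
#' @return The catalog with the mapping attached.
#' @export
set_tissue_cohorts <- function(catalog, map) {
  gene_catalog(catalog$sets, catalog$set_kind, catalog$universe, map)
}

#' Construct an undirected protein-protein interaction network
#'
#' Self-loops are dropped with a warning; duplicate and reversed-duplicate
#' edges are collapsed so each unordered pair is stored once.
#'
#' @param edges Two-column data frame or matrix of gene symbols.
#' @param nodes Optional extra isolated nodes; the node set is always the
#'   union of `nodes` and all edge endpoints.
#'
#' @return An object of class `ppi_network` with elements `nodes` and
#'   `edges` (tibble with columns `from`, `to`, `from < to` lexically).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- tibble(from = character(), to = character())
  } else {
    if (NCOL(edges) != 2) abort_format("`edges` must have exactly 2 columns")
    if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges <- tibble(from = as.character(edges[[1]]),
                    to = as.character(edges[[2]]))
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- dplyr::distinct(tibble(from = a, to = b))
  edges <- arrange(edges, .data$from, .data$to)
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' First neighbors of a gene in a PPI network
#'
#' @param network A [ppi_network()].
#' @param gene Gene symbol.
#' @return Character vector of neighbors (excluding the gene itself); empty
#'   with a warning if the gene is not a network node.
#' @export
ppi_neighbors <- function(network, gene) {
  if (!(gene %in% network$nodes)) {
    warn(sprintf("gene %s is not in the network", gene))
    return(character())
  }
  e <- network$edges
  unique(c(e$to[e$from == gene], e$from[e$to == gene]))
}
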