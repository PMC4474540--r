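#' Rank RNA-binding proteins by fold-change amplitude
#'
#' Differentially expressed RBPs sorted by `|log2fc|` descending, ties
#' broken by adjusted p ascending then symbol lexicographic, truncated to
#' the top `top_k` (default 20, the usual "top RBPs with highest fold
#' change" list).  Restricting to DE RBPs avoids ranking high-fold-change
#' genes that never reach significance; set `de_only = FALSE` to rank all
#' measured RBPs.
#'
#' @param de A `de_table` from [call_de()].
#' @param catalog A [gene_catalog()] containing the RBP set.
#' @param top_k Maximum list length (default 20).
#' @param rbp_set Name of the RBP set in the catalog.
#' @param de_only Rank only DE RBPs (default TRUE).
#' @return Tibble `gene`, `log2fc`, `abs_log2fc`, `p_adj` in rank order;
#'   shorter than `top_k` with a warning when fewer RBPs qualify.
#' @export
rank_rbps <- function(de, catalog, top_k = 20, rbp_set = "RBP",
                      de_only = TRUE) {
  if (!rbp_set %in% names(catalog$sets)) {
    abort(sprintf("set %s not present in catalog", rbp_set))
  }
  rows <- de[de$gene %in% catalog$sets[[rbp_set]], ]
  if (de_only) rows <- rows[rows$is_de, ]
  rows <- mutate(as_tibble(rows), abs_log2fc = abs(.data$log2fc))
  rows <- arrange(rows, desc(.data$abs_log2fc), .data$p_adj, .data$gene)
  if (nrow(rows) < top_k) {
    warn(sprintf("only %d qualifying RBP(s) for top_k = %d", nrow(rows), top_k))
  }
  select(head(rows, top_k), "gene", "log2fc", "abs_log2fc", "p_adj")
}

#' Cascade selection of RBPs whose PPI neighborhoods carry the dysregulation
#'
#' For each top-ranked RBP, its first PPI neighbors are tested for dual
#' over-representation — of differentially expressed genes and of
#' cancer-related (allOnco) genes — by two hypergeometric tails on the
#' universe of cohort-measured genes that are network nodes.  An RBP is
#' selected as a cascade RBP when both tails fall below `threshold`
#' (no correction across the top-k tests).  The exported subnetwork keeps
#' the selected RBPs and their neighbors that are both DE and allOnco (the
#' classic red-RBP / yellow-target display).
#'
#' @inheritParams rank_rbps
#' @param network A [ppi_network()].
#' @param threshold Dual-criterion significance threshold (default 0.05).
#' @param onco_set Name of the cancer-related gene set.
#' @return Object of class `cascade_result`: `rbp_stats` (per ranked RBP:
#'   neighbor count, overlap counts, both enrichment tails, `selected`),
#'   `subnetwork` ([ppi_network()]), `nodes` (role annotations for export),
#'   plus universe bookkeeping.
#' @export
cascade_select <- function(de, catalog, network, top_k = 20, threshold = 0.05,
                           rbp_set = "RBP", onco_set = "allOnco",
                           de_only = TRUE) {
  for (s in c(rbp_set, onco_set)) {
    if (!s %in% names(catalog$sets)) {
      abort(sprintf("set %s not present in catalog", s))
    }
  }
  universe <- intersect(de$gene, network$nodes)
  de_genes <- intersect(de$gene[de$is_de], universe)
  onco <- intersect(catalog$sets[[onco_set]], universe)
  ranked <- rank_rbps(de, catalog, top_k = top_k, rbp_set = rbp_set,
                      de_only = de_only)
  N <- length(universe)
  stats <- purrr::map_dfr(seq_len(nrow(ranked)), function(i) {
    g <- ranked$gene[i]
    nb <- if (g %in% network$nodes) {
      intersect(ppi_neighbors(network, g), universe)
    } else character()
    n_nb <- length(nb)
    k_de <- length(intersect(nb, de_genes))
    k_onco <- length(intersect(nb, onco))
    p_de <- hypergeom_enrichment(N, length(de_genes), n_nb, k_de)$p_enrich
    p_onco <- hypergeom_enrichment(N, length(onco), n_nb, k_onco)$p_enrich
    tibble(gene = g, log2fc = ranked$log2fc[i],
           abs_log2fc = ranked$abs_log2fc[i], p_adj = ranked$p_adj[i],
           n_neighbors = n_nb, k_de = k_de, k_onco = k_onco,
           p_enrich_de = p_de, p_enrich_onco = p_onco,
           selected = p_de < threshold & p_onco < threshold)
  })
  if (nrow(stats) == 0) {
    stats <- tibble(gene = character(), log2fc = double(),
                    abs_log2fc = double(), p_adj = double(),
                    n_neighbors = integer(), k_de = integer(),
                    k_onco = integer(), p_enrich_de = double(),
                    p_enrich_onco = double(), selected = logical())
  }
  sel <- stats$gene[stats$selected]
  targets <- intersect(de_genes, onco)
  keep <- (network$edges$from %in% sel &
             network$edges$to %in% c(sel, targets)) |
          (network$edges$to %in% sel &
             network$edges$from %in% c(sel, targets))
  sub_edges <- network$edges[keep, , drop = FALSE]
  subnetwork <- ppi_network(sub_edges, nodes = sel)
  nodes <- tibble(gene = subnetwork$nodes,
                  role = ifelse(subnetwork$nodes %in% sel, "rbp",
                                "allOnco_target"))
  structure(
    list(cohort_id = de_cohort_id(de), rbp_stats = stats,
         subnetwork = subnetwork, nodes = nodes,
         universe_size = N, n_de = length(de_genes), n_onco = length(onco),
         top_k = top_k, threshold = threshold),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "<cascade_result> %s: %d ranked RBPs, %d selected; subnetwork %d nodes / %d edges\n",
    x$cohort_id %||% "?", nrow(x$rbp_stats), sum(x$rbp_stats$selected),
    length(x$subnetwork$nodes), nrow(x$subnetwork$edges)))
  invisible(x)
}
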