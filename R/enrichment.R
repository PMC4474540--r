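#' Hypergeometric enrichment and depletion tails
#'
#' For a universe of `N` genes containing a set of size `K`, and `n` drawn
#' genes (here: the differentially expressed set) of which `k` fall in the
#' set, returns the one-sided over-representation tail
#' `p_enrich = P(X >= k)` and the under-representation tail
#' `p_deplete = P(X <= k)` for `X ~ Hypergeometric(N, K, n)`.  Both tails
#' include the observed point, so `p_enrich + p_deplete >= 1`.  Computed via
#' [stats::phyper()], which is log-space stable for large universes.
#'
#' All arguments are vectorised and recycled.
#'
#' @param N Universe size.
#' @param K Set size within the universe.
#' @param n Number of drawn (DE) genes.
#' @param k Overlap between the set and the drawn genes.
#' @return Tibble with columns `p_enrich`, `p_deplete`.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(N, len); K <- rep_len(K, len)
  n <- rep_len(n, len); k <- rep_len(k, len)
  if (any(K < 0 | K > N)) abort("require 0 <= K <= N")
  if (any(n < 0 | n > N)) abort("require 0 <= n <= N")
  if (any(k < pmax(0, n + K - N))) abort("require k >= max(0, n + K - N)")
  if (any(k > pmin(K, n))) abort("require k <= min(K, n)")
  tibble(
    p_enrich = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_deplete = phyper(k, K, N - K, n, lower.tail = TRUE)
  )
}

#' Category x cohort enrichment/depletion matrix
#'
#' For every (set, cohort) cell, overlaps are counted on the cohort's own
#' measured-gene universe (sets are restricted first, as in
#' [intersect_universe()]) and both hypergeometric tails are computed.  A
#' cell's direction is `enriched` or `depleted` when the corresponding tail
#' is at or below `threshold`, `neither` otherwise — mirroring the usual
#' heatmap display that whitens cells above 0.05.  No multiple-testing
#' correction is applied across the matrix; the tails are reported raw.
#'
#' @param de_tables A `de_table` or (optionally named) list of them.
#' @param catalog A [gene_catalog()].
#' @param sets Set names to test (default: all category-kind sets).
#' @param threshold Display threshold for direction (default 0.05).
#' @return Tibble of class `enrichment_matrix`, one row per (cohort, set):
#'   `cohort_id`, `set_name`, `N`, `K`, `n`, `k`, `p_enrich`, `p_deplete`,
#'   `direction`.
#' @export
enrichment_matrix <- function(de_tables, catalog, sets = NULL,
                              threshold = 0.05) {
  if (inherits(de_tables, "de_table")) de_tables <- list(de_tables)
  sets <- sets %||% sets_of_kind(catalog, "category")
  unknown <- setdiff(sets, names(catalog$sets))
  if (length(unknown) > 0) {
    abort(sprintf("unknown set(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- purrr::map_dfr(de_tables, function(de) {
    genes <- de$gene
    de_genes <- genes[de$is_de]
    purrr::map_dfr(sets, function(s) {
      members <- intersect(catalog$sets[[s]], genes)
      tibble(cohort_id = de_cohort_id(de), set_name = s,
             N = length(genes), K = length(members),
             n = length(de_genes), k = length(intersect(members, de_genes)))
    })
  })
  out <- dplyr::bind_cols(out, hypergeom_enrichment(out$N, out$K, out$n, out$k))
  out$direction <- ifelse(out$p_enrich <= threshold, "enriched",
                          ifelse(out$p_deplete <= threshold, "depleted",
                                 "neither"))
  structure(out, class = c("enrichment_matrix", class(tibble())),
            threshold = threshold)
}

#' Tissue-specific gene analysis for a cohort
#'
#' Tests whether the tissue-specific gene set matched to this cohort is
#' over-represented among its differentially expressed genes, and — among
#' the DE tissue genes — what fraction is under-expressed in tumor
#' (`log2fc < 0`), with an exact two-sided binomial sign test against 0.5
#' and a one-sided rank-sum comparison of their signed log2 fold changes
#' against all other DE genes (alternative: tissue genes shift lower).
#'
#' @param de A `de_table` from [call_de()].
#' @param catalog A [gene_catalog()] whose `tissue_to_cohort` maps exactly
#'   one tissue set to this cohort (otherwise skipped with a warning).
#' @param threshold Direction threshold for the enrichment cell.
#' @return One-row tibble of class `tissue_report`, or `NULL` when no
#'   matched tissue set exists.
#' @export
tissue_specificity <- function(de, catalog, threshold = 0.05) {
  cid <- de_cohort_id(de)
  tset <- names(catalog$tissue_to_cohort)[catalog$tissue_to_cohort == cid]
  if (length(tset) != 1) {
    warn(sprintf("cohort %s: %d matched tissue set(s); skipping", cid,
                 length(tset)))
    return(NULL)
  }
  genes <- de$gene
  members <- intersect(catalog$sets[[tset]], genes)
  de_genes <- genes[de$is_de]
  k <- length(intersect(members, de_genes))
  cell <- hypergeom_enrichment(length(genes), length(members),
                               length(de_genes), k)
  lfc <- setNames(de$log2fc, de$gene)
  tissue_de <- intersect(members, de_genes)
  other_de <- setdiff(de_genes, members)
  n_under <- sum(lfc[tissue_de] < 0)
  sign_p <- if (k > 0) binom.test(n_under, k, p = 0.5)$p.value else NA_real_
  rank_p <- if (k > 0 && length(other_de) > 0) {
    suppressWarnings(
      wilcox.test(lfc[tissue_de], lfc[other_de], alternative = "less")$p.value
    )
  } else NA_real_
  out <- tibble(
    cohort_id = cid, tissue_set = tset,
    N = length(genes), K = length(members), n = length(de_genes), k = k,
    p_enrich = cell$p_enrich, p_deplete = cell$p_deplete,
    direction = ifelse(cell$p_enrich <= threshold, "enriched",
                       ifelse(cell$p_deplete <= threshold, "depleted",
                              "neither")),
    n_de_tissue = k, n_under = n_under,
    frac_under = ifelse(k > 0, n_under / k, NA_real_),
    sign_test_p = sign_p, ranksum_p = rank_p
  )
  structure(out, class = c("tissue_report", class(tibble())))
}
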