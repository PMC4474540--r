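#' Paired log2 fold change
#'
#' Fold change is the mean over matched pairs of the per-pair log2 ratio
#' `log2((T_i + c) / (N_i + c))` with pseudocount `c`, consistent with the
#' paired design and always finite.
#'
#' @param tumor,normal Equal-length vectors of non-negative expression values.
#' @param pseudocount Positive pseudocount added to both sides (default 1).
#' @return The paired log2 fold change (a single number).
#' @export
paired_log2fc <- function(tumor, normal, pseudocount = 1) {
  if (length(tumor) != length(normal)) {
    abort("`tumor` and `normal` must have the same length")
  }
  if (length(tumor) < 1) abort("need at least one pair")
  stopifnot(pseudocount > 0)
  mean(log2((tumor + pseudocount) / (normal + pseudocount)))
}

#' Paired two-sided t-test on matched tumor/normal values
#'
#' Student t on the per-pair differences `tumor - normal` with `n - 1`
#' degrees of freedom.  Callers testing expression pass log-transformed
#' values (see [call_de()]).  When every difference is exactly zero the
#' statistic is undefined and p = 1 is returned, so degenerate genes stay in
#' the universe without ever being called differentially expressed.
#'
#' @param tumor,normal Equal-length numeric vectors, at least 2 pairs.
#' @return List with `t_stat` (NA when undefined), `df`, `p_value`.
#' @export
paired_t_test <- function(tumor, normal) {
  if (length(tumor) != length(normal)) {
    abort("`tumor` and `normal` must have the same length")
  }
  n <- length(tumor)
  if (n < 2) abort("paired t-test needs at least 2 pairs")
  d <- tumor - normal
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t_stat = NA_real_, df = n - 1, p_value = 1))
    return(list(t_stat = sign(m) * Inf, df = n - 1, p_value = 0))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat, df = n - 1,
       p_value = 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` with `m` the number of tests (the vector length).
#'
#' @param p_raw Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni <- function(p_raw) {
  if (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_raw, method = "bonferroni")
}

#' Per-gene paired differential expression for one cohort
#'
#' Applies the paired t-test to `log2(x + pseudocount)`-transformed values
#' of every gene, adjusts with Bonferroni over all tested genes in the
#' cohort, and flags genes differentially expressed at `p_adj < alpha`.
#' The reported `log2fc` is the paired log2 fold change ([paired_log2fc()]),
#' which on this transform equals the mean paired difference being tested.
#'
#' @inheritParams cohort_genes
#' @param alpha Family-wise significance level on adjusted p (default 0.05).
#' @param pseudocount Positive pseudocount for the log transform (default 1).
#' @return A tibble of class `de_table` with one row per gene: `gene`,
#'   `mean_normal`, `mean_tumor`, `log2fc`, `t_stat`, `df`, `p_raw`,
#'   `p_adj`, `is_de`.  Cohort id, alpha, pseudocount and pair count are
#'   attached as attributes.
#' @export
call_de <- function(cohort, alpha = 0.05, pseudocount = 1) {
  stopifnot(inherits(cohort, "paired_cohort"), is_prob(alpha), pseudocount > 0)
  tum <- tumor_matrix(cohort)
  nor <- normal_matrix(cohort)
  n <- ncol(tum)
  d <- log2(tum + pseudocount) - log2(nor + pseudocount)
  m <- rowMeans(d)
  s <- row_sds(d)
  t_stat <- m / (s / sqrt(n))
  p_raw <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  # degenerate genes: identical tumor/normal vectors stay with p = 1
  zero_sd <- s == 0
  t_stat[zero_sd & m == 0] <- NA_real_
  p_raw[zero_sd & m == 0] <- 1
  p_raw[zero_sd & m != 0] <- 0
  p_adj <- bonferroni(p_raw)
  out <- tibble(
    gene = rownames(tum),
    mean_normal = unname(rowMeans(nor)),
    mean_tumor = unname(rowMeans(tum)),
    log2fc = unname(m),
    t_stat = unname(t_stat),
    df = n - 1,
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    is_de = p_adj < alpha
  )
  new_de_table(out, cohort_id = cohort$cohort_id, alpha = alpha,
               pseudocount = pseudocount, n_pairs = n)
}

new_de_table <- function(x, cohort_id, alpha, pseudocount, n_pairs) {
  structure(x, class = c("de_table", class(tibble())),
            cohort_id = cohort_id, alpha = alpha,
            pseudocount = pseudocount, n_pairs = n_pairs)
}

#' Cohort id of a DE table
#' @param de A `de_table` from [call_de()].
#' @return Single string.
#' @export
de_cohort_id <- function(de) attr(de, "cohort_id", exact = TRUE)

#' Write / read a DE table as TSV
#' @param de A `de_table`.
#' @param path TSV path.
#' @return [read_de_table()] returns a `de_table`.
#' @export
write_de_table <- function(de, path) {
  tab <- as_tibble(de)
  tab$cohort_id <- de_cohort_id(de)
  write_atomic(path, function(p) readr::write_tsv(tab, p, progress = FALSE))
  invisible(path)
}

#' @rdname write_de_table
#' @param alpha,pseudocount,n_pairs Metadata to re-attach (alpha defaults
#'   to 0.05 as in [call_de()]).
#' @export
read_de_table <- function(path, alpha = 0.05, pseudocount = 1, n_pairs = NA) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cid <- unique(tab$cohort_id)
  stopifnot(length(cid) == 1)
  tab$cohort_id <- NULL
  new_de_table(as_tibble(tab), cohort_id = cid, alpha = alpha,
               pseudocount = pseudocount, n_pairs = n_pairs)
}

#' Fold-change amplitude profiles of gene sets
#'
#' For each requested set, collects the absolute log2 fold changes of its
#' differentially expressed members, exposes their empirical CDFs (the
#' classic per-cohort CDF comparison of alteration amplitude across gene
#' categories), and adds pairwise one-sided rank-sum tests of "set A's DE
#' amplitudes are larger than set B's".  The rank-sum comparison is an
#' extension beyond the purely descriptive CDF display.
#'
#' @param de A `de_table` from [call_de()].
#' @param catalog A [gene_catalog()].
#' @param sets Character vector of set names (default: all category-kind
#'   sets).
#' @return Object of class `amplitude_profile`: `values` (tibble `set_name`,
#'   `gene`, `abs_log2fc`), `ecdfs` (named list of ECDF functions for
#'   non-empty sets), `comparisons` (tibble with one-sided `p_greater` for
#'   each ordered pair), `empty_sets`.
#' @export
amplitude_profiles <- function(de, catalog, sets = NULL) {
  sets <- sets %||% sets_of_kind(catalog, "category")
  unknown <- setdiff(sets, names(catalog$sets))
  if (length(unknown) > 0) {
    abort(sprintf("unknown set(s): %s", paste(unknown, collapse = ", ")))
  }
  de_genes <- de$gene[de$is_de]
  lfc <- setNames(abs(de$log2fc), de$gene)
  values <- purrr::map_dfr(sets, function(s) {
    members <- intersect(catalog$sets[[s]], de_genes)
    tibble(set_name = s, gene = members, abs_log2fc = unname(lfc[members]))
  })
  empty <- setdiff(sets, unique(values$set_name))
  ecdfs <- lapply(
    setNames(setdiff(sets, empty), setdiff(sets, empty)),
    function(s) ecdf(values$abs_log2fc[values$set_name == s])
  )
  pairs <- expand.grid(set_a = setdiff(sets, empty),
                       set_b = setdiff(sets, empty),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$set_a != pairs$set_b, , drop = FALSE]
  comparisons <- purrr::pmap_dfr(pairs, function(set_a, set_b) {
    a <- values$abs_log2fc[values$set_name == set_a]
    b <- values$abs_log2fc[values$set_name == set_b]
    w <- suppressWarnings(wilcox.test(a, b, alternative = "greater"))
    tibble(set_a = set_a, set_b = set_b,
           n_a = length(a), n_b = length(b),
           w_stat = unname(w$statistic), p_greater = w$p.value)
  })
  structure(
    list(cohort_id = de_cohort_id(de), values = values, ecdfs = ecdfs,
         comparisons = comparisons, empty_sets = empty),
    class = "amplitude_profile"
  )
}

#' @export
print.amplitude_profile <- function(x, ...) {
  cat(sprintf("<amplitude_profile> %s: %d sets, %d DE amplitude values\n",
              x$cohort_id %||% "?", length(x$ecdfs), nrow(x$values)))
  invisible(x)
}
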