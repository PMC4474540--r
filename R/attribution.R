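#' Spearman rank correlation (tie-robust)
#'
#' Pearson correlation of average ranks, i.e. [stats::cor()] with
#' `method = "spearman"`.  Returns `NA` when either vector has zero rank
#' variance (the gene is then excluded upstream rather than erroring).
#'
#' @param x,y Equal-length numeric vectors with at least 3 entries.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Per-pair log2 expression change matrix
#'
#' `log2((T + c) / (N + c))` for every gene and matched pair; columns are
#' named by `patient_id` so they can be matched to molecular matrices.
#'
#' @inheritParams cohort_genes
#' @param pseudocount Positive pseudocount (default 1).
#' @return Numeric matrix genes x pairs.
#' @export
pair_log2_change <- function(cohort, pseudocount = 1) {
  d <- log2(tumor_matrix(cohort) + pseudocount) -
    log2(normal_matrix(cohort) + pseudocount)
  colnames(d) <- cohort$pairs$patient_id
  d
}

#' Attribute per-gene expression changes to a molecular assay
#'
#' For each RBP, pairs its per-patient log2 expression change with the
#' molecular value (copy-number log-ratio or methylation level) in the
#' matched tumor sample, and records the Spearman correlation and its
#' square — the fraction of rank variation in expression change that the
#' assay can explain.  Genes absent from the assay matrix, with fewer than
#' `min_samples` matched patients, or with degenerate (zero rank variance)
#' profiles are excluded and counted.
#'
#' @inheritParams pair_log2_change
#' @param mat A [molecular_matrix()] whose columns are patient ids.
#' @param de A `de_table` supplying each RBP's DE status.
#' @param catalog A [gene_catalog()] containing the RBP set.
#' @param rbp_set Name of the RBP set.
#' @param min_samples Minimum matched patients for a meaningful rank
#'   correlation (default 8).
#' @return Object of class `attribution_table`: `rows` (tibble `gene`,
#'   `n_samples`, `rho`, `r_squared`, `de_status`), `excluded` (tibble
#'   `gene`, `reason`), plus cohort/assay metadata.
#' @export
per_gene_attribution <- function(cohort, mat, de, catalog, rbp_set = "RBP",
                                 pseudocount = 1, min_samples = 8) {
  stopifnot(inherits(mat, "molecular_matrix"))
  if (!rbp_set %in% names(catalog$sets)) {
    abort(sprintf("set %s not present in catalog", rbp_set))
  }
  d <- pair_log2_change(cohort, pseudocount)
  shared <- intersect(colnames(d), colnames(mat$values))
  rbps <- intersect(catalog$sets[[rbp_set]], rownames(d))
  de_status <- setNames(de$is_de, de$gene)
  rows <- list(); excluded <- list()
  for (g in rbps) {
    if (!g %in% rownames(mat$values)) {
      excluded[[g]] <- "absent_from_matrix"; next
    }
    x <- d[g, shared]
    y <- mat$values[g, shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples) {
      excluded[[g]] <- "too_few_samples"; next
    }
    rho <- spearman_rho(x[ok], y[ok])
    if (is.na(rho)) {
      excluded[[g]] <- "degenerate"; next
    }
    rows[[g]] <- tibble(gene = g, n_samples = sum(ok), rho = rho,
                        r_squared = rho^2,
                        de_status = unname(de_status[g]))
  }
  structure(
    list(cohort_id = cohort$cohort_id, assay = mat$assay,
         rows = bind_rows(rows),
         excluded = tibble(gene = names(excluded),
                           reason = unlist(excluded, use.names = FALSE) %||% character()),
         min_samples = min_samples),
    class = "attribution_table"
  )
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("<attribution_table> %s / %s: %d genes (%d excluded)\n",
              x$cohort_id, x$assay, nrow(x$rows), nrow(x$excluded)))
  invisible(x)
}

#' Compare explained variation between DE and non-DE RBPs
#'
#' One-sided Wilcoxon rank-sum test of the alternative that differentially
#' expressed RBPs have larger `r_squared` than non-DE RBPs.  The exact null
#' distribution is used when both groups have at most 10 members and the
#' values are tie-free; otherwise the normal approximation with tie
#' correction.
#'
#' @param att An `attribution_table` from [per_gene_attribution()].
#' @param alternative Test direction (default `"greater"`).
#' @return One-row tibble: `w_stat`, `p_value`, `method`, `alternative`,
#'   `n_de`, `n_non_de`, `cohort_id`, `assay`.
#' @export
compare_groups <- function(att, alternative = "greater") {
  rows <- att$rows
  x <- rows$r_squared[rows$de_status]
  y <- rows$r_squared[!rows$de_status]
  if (length(x) == 0) abort("the DE group is empty")
  if (length(y) == 0) abort("the non-DE group is empty")
  exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
  w <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact)
  )
  tibble(w_stat = unname(w$statistic), p_value = w$p.value,
         method = ifelse(exact, "exact", "normal_approx"),
         alternative = alternative,
         n_de = length(x), n_non_de = length(y),
         cohort_id = att$cohort_id, assay = att$assay)
}
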