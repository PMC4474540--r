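#' Construct a paired tumor/normal expression cohort
#'
#' A paired cohort bundles one cancer type's gene-by-sample expression matrix
#' with the table that pairs each patient's tumor column to their matched
#' normal column.  Expression values are taken as already-normalized,
#' non-negative abundances; no re-normalization is performed.
#'
#' @param expr Numeric matrix of non-negative expression values, genes in
#'   rows (unique, whitespace-free symbols as rownames), samples in columns.
#' @param pairs Data frame with columns `patient_id`, `tumor_sample`,
#'   `normal_sample`; every sample name must be a column of `expr` and the
#'   two columns of a pair must differ.
#' @param cohort_id Single string naming the cohort (e.g. `"BRCA"`).
#'
#' @return An object of class `paired_cohort`.
#' @export
paired_cohort <- function(expr, pairs, cohort_id) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort_format("`expr` must be a numeric matrix")
  }
  genes <- rownames(expr)
  if (is.null(genes) || anyNA(genes) || any(genes == "")) {
    abort_format("expression matrix must have non-empty gene symbols as rownames")
  }
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    abort_format(sprintf("duplicate gene symbol(s): %s",
                         paste(unique(dup), collapse = ", ")))
  }
  if (any(grepl("\\s", genes))) {
    abort_format("gene symbols must not contain whitespace")
  }
  if (anyNA(expr)) abort_format("expression matrix contains missing values")
  if (any(expr < 0)) {
    bad <- genes[which(rowSums(expr < 0) > 0)[1]]
    abort_format(sprintf("negative expression value found (gene %s)", bad))
  }
  pairs <- as_tibble(pairs)
  need <- c("patient_id", "tumor_sample", "normal_sample")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) {
    abort_format(sprintf("pairing table lacks column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  pairs <- pairs[need]
  if (nrow(pairs) < 2) abort_format("a cohort needs at least 2 tumor/normal pairs")
  if (anyDuplicated(pairs$patient_id)) {
    abort_format("duplicate patient_id in pairing table")
  }
  ref <- c(pairs$tumor_sample, pairs$normal_sample)
  absent <- setdiff(ref, colnames(expr))
  if (length(absent) > 0) {
    abort_format(sprintf(
      "pairing table references column(s) absent from the expression matrix: %s",
      paste(unique(absent), collapse = ", ")))
  }
  if (any(pairs$tumor_sample == pairs$normal_sample)) {
    abort_format("a pair must reference two distinct columns")
  }
  if (!is.character(cohort_id) || length(cohort_id) != 1 || is.na(cohort_id)) {
    abort_format("`cohort_id` must be a single string")
  }
  structure(
    list(cohort_id = cohort_id, expr = expr, pairs = pairs),
    class = "paired_cohort"
  )
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %s: %d genes, %d tumor/normal pairs\n",
              x$cohort_id, nrow(x$expr), nrow(x$pairs)))
  invisible(x)
}

#' Genes measured in a cohort
#' @param cohort A [paired_cohort()].
#' @return Character vector of gene symbols in matrix order.
#' @export
cohort_genes <- function(cohort) rownames(cohort$expr)

#' Number of tumor/normal pairs in a cohort
#' @inheritParams cohort_genes
#' @return Integer.
#' @export
n_pairs <- function(cohort) nrow(cohort$pairs)

#' Tumor and normal submatrices in pair order
#' @inheritParams cohort_genes
#' @return Numeric matrix genes x pairs; columns follow the pairing table.
#' @export
tumor_matrix <- function(cohort) {
  cohort$expr[, cohort$pairs$tumor_sample, drop = FALSE]
}

#' @rdname tumor_matrix
#' @export
normal_matrix <- function(cohort) {
  cohort$expr[, cohort$pairs$normal_sample, drop = FALSE]
}

#' Construct a gene-level molecular matrix (copy number or methylation)
#'
#' @param values Numeric matrix, genes in rows, tumor samples in columns.
#'   Columns are named by `patient_id` so they can be matched to the tumor
#'   columns of a [paired_cohort()].  Copy-number values are log2
#'   copy-ratios; methylation values must lie in \[0, 1\].
#' @param assay `"cnv"` or `"methylation"`.
#'
#' @return An object of class `molecular_matrix`.
#' @export
molecular_matrix <- function(values, assay = c("cnv", "methylation")) {
  assay <- match.arg(assay)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_format("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_format("molecular matrix needs gene rownames and sample colnames")
  }
  if (assay == "methylation" &&
      any(values < 0 | values > 1, na.rm = TRUE)) {
    abort_format("methylation values must lie in [0, 1]")
  }
  structure(list(assay = assay, values = values), class = "molecular_matrix")
}

#' @export
print.molecular_matrix <- function(x, ...) {
  cat(sprintf("<molecular_matrix> %s: %d genes x %d samples\n",
              x$assay, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Restrict catalog, network and molecular matrices to a cohort's universe
#'
#' The analysis universe for every downstream statistic is the set of genes
#' actually measured in a cohort's expression matrix; category sets, network
#' edges and molecular profiles for unmeasured genes are invisible to that
#' cohort.  (In the motivating data, e.g., only a few hundred of several
#' thousand annotated lncRNAs appear in standardized mRNA-Seq matrices.)
#'
#' Restriction is idempotent, never enlarges a set, and never alters the
#' cohort's expression values.
#'
#' @inheritParams cohort_genes
#' @param catalog Optional [gene_catalog()].
#' @param network Optional [ppi_network()].
#' @param mats Optional [molecular_matrix()] or list thereof.
#'
#' @return A list of class `restricted_views` with elements `cohort`,
#'   `catalog`, `network`, `mats` and a `retained` tibble reporting, for each
#'   catalog set, its original and retained size.
#' @export
intersect_universe <- function(cohort, catalog = NULL, network = NULL,
                               mats = NULL) {
  genes <- cohort_genes(cohort)
  retained <- tibble(set_name = character(), original = integer(),
                     retained = integer())
  if (!is.null(catalog)) {
    before <- lengths(catalog$sets)
    catalog$universe <- intersect(catalog$universe, genes)
    catalog$sets <- lapply(catalog$sets, intersect, y = genes)
    after <- lengths(catalog$sets)
    emptied <- names(catalog$sets)[before > 0 & after == 0]
    if (length(emptied) > 0) {
      warn(sprintf("restriction to cohort %s left set(s) empty: %s",
                   cohort$cohort_id, paste(emptied, collapse = ", ")))
    }
    retained <- tibble(set_name = names(catalog$sets),
                       original = as.integer(before),
                       retained = as.integer(after))
  }
  if (!is.null(network)) {
    keep <- network$edges$from %in% genes & network$edges$to %in% genes
    network$edges <- network$edges[keep, , drop = FALSE]
    network$nodes <- intersect(network$nodes, genes)
  }
  if (!is.null(mats)) {
    single <- inherits(mats, "molecular_matrix")
    if (single) mats <- list(mats)
    mats <- lapply(mats, function(m) {
      m$values <- m$values[intersect(rownames(m$values), genes), , drop = FALSE]
      m
    })
    if (single) mats <- mats[[1]]
  }
  structure(
    list(cohort = cohort, catalog = catalog, network = network, mats = mats,
         retained = retained),
    class = "restricted_views"
  )
}
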