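#' Fold-change correlation distance between cohorts
#'
#' `d(a, b) = 1 - spearman_rho(log2fc_a, log2fc_b)` over the genes shared by
#' all cohorts (optionally intersected with a pathway's members).  All
#' shared genes contribute, not only the significant ones; anticorrelated
#' cohorts therefore sit near distance 2.
#'
#' @param de_tables List of at least two `de_table`s.
#' @param genes Optional gene subset (e.g. a pathway); default all shared.
#' @param label Label used in error messages and carried to dendrograms.
#' @param min_genes Minimum shared genes required (default 10).
#' @return Symmetric distance matrix with zero diagonal; attributes
#'   `n_genes` and `label`.
#' @export
fold_change_distance <- function(de_tables, genes = NULL,
                                 label = "all_genes", min_genes = 10) {
  if (length(de_tables) < 2) abort("need at least 2 cohorts")
  ids <- vapply(de_tables, de_cohort_id, character(1))
  shared <- Reduce(intersect, lapply(de_tables, function(d) d$gene))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < min_genes) {
    abort(sprintf("%s: only %d shared gene(s); need at least %d",
                  label, length(shared), min_genes))
  }
  mat <- vapply(de_tables, function(d) {
    setNames(d$log2fc, d$gene)[shared]
  }, numeric(length(shared)))
  colnames(mat) <- ids
  d <- 1 - cor(mat, method = "spearman")
  diag(d) <- 0
  attr(d, "n_genes") <- length(shared)
  attr(d, "label") <- label
  d
}

#' Agglomerative clustering of cohorts (average linkage)
#'
#' UPGMA on a correlation-distance matrix with a deterministic tie rule:
#' among pairs at the minimal distance (within 1e-12), the pair whose
#' smallest member labels sort first lexicographically is merged.  Average
#' linkage guarantees non-decreasing merge heights.  A Newick string with
#' ultrametric branch lengths (merge height / 2, rounded at 6 decimals) is
#' emitted for exchange.
#'
#' @param dist Symmetric distance matrix with zero diagonal and labelled
#'   dimnames (or `cohort_ids` given).
#' @param cohort_ids Leaf labels; default `colnames(dist)`.
#' @param label Dendrogram label (e.g. pathway name).
#' @return Object of class `cohort_dendrogram`: `labels`, `merge` and
#'   `height` (hclust encoding), `order`, `newick`, `n_genes`, `dist`.
#' @export
cluster_cohorts <- function(dist, cohort_ids = NULL, label = NULL) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    abort("`dist` must be a square matrix")
  }
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    abort("`dist` must be symmetric")
  }
  labels <- cohort_ids %||% colnames(dist)
  if (is.null(labels)) abort("cohort ids are required")
  n <- nrow(dist)
  if (n < 2) abort("need at least 2 cohorts")
  d <- unname(dist)
  # active clusters: hclust codes (-i singleton, +row merged), sizes, and the
  # lexicographically smallest member label for tie-breaking
  code <- -seq_len(n)
  size <- rep(1L, n)
  minlab <- labels
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  active <- seq_len(n)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    dm <- d[active, active, drop = FALSE]
    dm[lower.tri(dm, diag = TRUE)] <- Inf
    lo <- min(dm)
    cand <- which(dm <= lo + 1e-12, arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      ls <- sort(c(minlab[active[ij[1]]], minlab[active[ij[2]]]))
      paste(ls, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    h <- d[i, j]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- h
    # average-linkage update, new cluster stored in slot i
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      upd <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- upd
      d[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    code[i] <- step
    active <- setdiff(active, j)
  }
  ord <- dendro_order(merge, n)
  nwk <- paste0(dendro_newick(n - 1, merge, height, labels), ";")
  structure(
    list(label = label %||% attr(dist, "label") %||% "all_genes",
         labels = labels, merge = merge, height = height, order = ord,
         newick = nwk, n_genes = attr(dist, "n_genes"), dist = dist),
    class = "cohort_dendrogram"
  )
}

# leaf order for plotting, left-to-right
dendro_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(n - 1)
}

# ultrametric newick: each child branch spans parent height/2 - child height/2
dendro_newick <- function(node, merge, height, labels) {
  h <- height[node]
  part <- function(child) {
    if (child < 0) {
      sprintf("%s:%s", labels[-child], format(round(h / 2, 6), scientific = FALSE))
    } else {
      sprintf("%s:%s", dendro_newick(child, merge, height, labels),
              format(round((h - height[child]) / 2, 6), scientific = FALSE))
    }
  }
  sprintf("(%s,%s)", part(merge[node, 1]), part(merge[node, 2]))
}

#' @export
print.cohort_dendrogram <- function(x, ...) {
  cat(sprintf("<cohort_dendrogram> %s: %d leaves over %s genes\n%s\n",
              x$label, length(x$labels),
              x$n_genes %||% "?", x$newick))
  invisible(x)
}

#' Convert a cohort dendrogram to an hclust object
#' @param x A `cohort_dendrogram`.
#' @param ... Unused.
#' @return A [stats::hclust] object.
#' @export
as.hclust.cohort_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "1 - spearman"),
            class = "hclust")
}

#' Pathway-restricted clustering panel
#'
#' One dendrogram over all shared genes plus one per pathway; per-pathway
#' failures (e.g. too few shared genes) are reported as warnings and the
#' panel continues.
#'
#' @inheritParams fold_change_distance
#' @param catalog A [gene_catalog()] with pathway-kind sets.
#' @param pathways Pathway set names (default: all pathway-kind sets).
#' @return Named list of class `dendrogram_panel` (`all_genes` first); an
#'   attribute `failures` records pathways that could not be clustered.
#' @export
pathway_panel <- function(de_tables, catalog, pathways = NULL,
                          min_genes = 10) {
  pathways <- pathways %||% sets_of_kind(catalog, "pathway")
  bad <- setdiff(pathways, sets_of_kind(catalog, "pathway"))
  if (length(bad) > 0) {
    abort(sprintf("not pathway-kind set(s): %s", paste(bad, collapse = ", ")))
  }
  out <- list(all_genes = cluster_cohorts(
    fold_change_distance(de_tables, label = "all_genes",
                         min_genes = min_genes)))
  failures <- character()
  for (p in pathways) {
    res <- tryCatch(
      cluster_cohorts(fold_change_distance(
        de_tables, genes = catalog$sets[[p]], label = p,
        min_genes = min_genes)),
      error = function(e) {
        warn(sprintf("pathway %s skipped: %s", p, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) out[[p]] <- res else failures <- c(failures, p)
  }
  structure(out, class = "dendrogram_panel", failures = failures)
}
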