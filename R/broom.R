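#' Tidiers for pipeline result objects
#'
#' `tidy()` returns the per-unit (gene, RBP, merge) tibble of a result;
#' `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name pandys-tidiers
NULL

#' @rdname pandys-tidiers
#' @method glance de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble(cohort_id = de_cohort_id(x), n_genes = nrow(x),
         n_pairs = attr(x, "n_pairs", exact = TRUE),
         n_de = sum(x$is_de),
         alpha = attr(x, "alpha", exact = TRUE),
         pseudocount = attr(x, "pseudocount", exact = TRUE))
}

#' @rdname pandys-tidiers
#' @method tidy amplitude_profile
#' @export
tidy.amplitude_profile <- function(x, ...) x$values

#' @rdname pandys-tidiers
#' @method glance amplitude_profile
#' @export
glance.amplitude_profile <- function(x, ...) {
  tibble(cohort_id = x$cohort_id, n_sets = length(x$ecdfs),
         n_values = nrow(x$values), n_empty_sets = length(x$empty_sets))
}

#' @rdname pandys-tidiers
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) x$rbp_stats

#' @rdname pandys-tidiers
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  tibble(cohort_id = x$cohort_id, n_ranked = nrow(x$rbp_stats),
         n_selected = sum(x$rbp_stats$selected),
         universe_size = x$universe_size, n_de = x$n_de, n_onco = x$n_onco,
         top_k = x$top_k, threshold = x$threshold)
}

#' @rdname pandys-tidiers
#' @method tidy attribution_table
#' @export
tidy.attribution_table <- function(x, ...) x$rows

#' @rdname pandys-tidiers
#' @method glance attribution_table
#' @export
glance.attribution_table <- function(x, ...) {
  cmp <- tryCatch(compare_groups(x), error = function(e) NULL)
  tibble(cohort_id = x$cohort_id, assay = x$assay,
         n_genes = nrow(x$rows), n_excluded = nrow(x$excluded),
         n_de = sum(x$rows$de_status), n_non_de = sum(!x$rows$de_status),
         wilcoxon_w = if (!is.null(cmp)) cmp$w_stat else NA_real_,
         wilcoxon_p = if (!is.null(cmp)) cmp$p_value else NA_real_)
}

#' @rdname pandys-tidiers
#' @method tidy cohort_dendrogram
#' @export
tidy.cohort_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  members <- function(node) {
    if (node < 0) return(x$labels[-node])
    c(members(x$merge[node, 1]), members(x$merge[node, 2]))
  }
  purrr::map_dfr(seq_len(n - 1), function(s) {
    tibble(step = s, height = x$height[s],
           members = paste(sort(members(s)), collapse = ","))
  })
}

#' @rdname pandys-tidiers
#' @method glance cohort_dendrogram
#' @export
glance.cohort_dendrogram <- function(x, ...) {
  tibble(label = x$label, n_leaves = length(x$labels),
         n_genes = x$n_genes %||% NA_integer_,
         max_height = max(x$height), newick = x$newick)
}
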