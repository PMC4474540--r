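#' Heatmap of the category x cohort enrichment matrix
#'
#' Cells are shaded by signed significance, `-log10(p)` toward red for
#' enrichment and toward blue for depletion; cells whose best tail exceeds
#' the display threshold are white.
#'
#' @param object An `enrichment_matrix` from [enrichment_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_matrix
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  threshold <- attr(object, "threshold", exact = TRUE) %||% 0.05
  df <- mutate(
    as_tibble(object),
    signed = dplyr::case_when(
      .data$direction == "enriched" ~ -log10(pmax(.data$p_enrich, 1e-300)),
      .data$direction == "depleted" ~ log10(pmax(.data$p_deplete, 1e-300)),
      TRUE ~ 0
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort_id, y = .data$set_name,
                                   fill = .data$signed)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0,
                                  name = expression(-log[10](p))) +
    ggplot2::labs(x = "cohort", y = "gene set",
                  subtitle = sprintf("white: p > %g on both tails", threshold)) +
    ggplot2::theme_minimal()
}

#' ECDF plot of fold-change amplitudes per gene set
#'
#' @param object An `amplitude_profile` from [amplitude_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amplitude_profile
#' @export
autoplot.amplitude_profile <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$abs_log2fc,
                               color = .data$set_name)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(x = expression("|" * log[2] ~ "fold change|"),
                  y = "cumulative fraction of DE genes", color = "gene set",
                  title = object$cohort_id) +
    ggplot2::theme_minimal()
}

#' Dual-enrichment plot of ranked RBP neighborhoods
#'
#' One point per ranked RBP at its neighborhood's DE-enrichment and
#' allOnco-enrichment tails (-log10); selected cascade RBPs are highlighted
#' and the dual threshold is drawn.
#'
#' @param object A `cascade_result` from [cascade_select()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  thr <- -log10(object$threshold)
  df <- mutate(object$rbp_stats,
               x = -log10(pmax(.data$p_enrich_de, 1e-300)),
               y = -log10(pmax(.data$p_enrich_onco, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$selected)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2, color = "grey50") +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, color = "grey50") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red")) +
    ggplot2::labs(x = expression(-log[10] ~ p[DE]),
                  y = expression(-log[10] ~ p[allOnco]),
                  color = "cascade RBP", title = object$cohort_id) +
    ggplot2::theme_minimal()
}

#' Boxplot of explained variation for DE vs non-DE RBPs
#'
#' @param object An `attribution_table` from [per_gene_attribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attribution_table
#' @export
autoplot.attribution_table <- function(object, ...) {
  df <- mutate(object$rows,
               group = ifelse(.data$de_status, "DE RBPs", "non-DE RBPs"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$r_squared)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  title = sprintf("%s — %s", object$cohort_id,
                                  object$assay)) +
    ggplot2::theme_minimal()
}

#' Dendrogram plot of cohort clustering
#'
#' @param object A `cohort_dendrogram` from [cluster_cohorts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_dendrogram
#' @export
autoplot.cohort_dendrogram <- function(object, ...) {
  n <- length(object$labels)
  # leaf x positions from the plotting order; internal nodes midway
  xpos <- numeric(n - 1); leafx <- match(seq_len(n), object$order)
  node_x <- function(node) if (node < 0) leafx[-node] else xpos[node]
  node_h <- function(node) if (node < 0) 0 else object$height[node]
  segs <- list()
  for (s in seq_len(n - 1)) {
    l <- object$merge[s, 1]; r <- object$merge[s, 2]
    xl <- node_x(l); xr <- node_x(r); h <- object$height[s]
    xpos[s] <- (xl + xr) / 2
    segs[[s]] <- tibble(
      x = c(xl, xr, xl), xend = c(xl, xr, xr),
      y = c(node_h(l), node_h(r), h), yend = c(h, h, h))
  }
  ggplot2::ggplot(bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leafx, labels = object$labels) +
    ggplot2::labs(x = NULL, y = "1 - Spearman correlation",
                  title = object$label) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}
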