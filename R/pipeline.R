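#' Validate a pipeline run configuration
#'
#' The configuration (a YAML file or an equivalent list) names all inputs
#' per cohort, the stage parameters, and the output directory.  All
#' violations are collected and reported together, not just the first.
#'
#' Recognised fields: `out_dir` (required); `cohorts` — a list of entries
#' with `id`, `expression`, `pairs` and optional `cnv` / `methylation`
#' paths; `gene_sets` — named GMT paths among `categories`, `tissues`,
#' `pathways`; optional `tissue_map` and `network` paths; stage parameters
#' `alpha` (0.05), `pseudocount` (1), `enrichment_threshold` (0.05),
#' `top_k` (20), `min_samples` (8), `pathways` (pathway names to cluster;
#' default all).
#'
#' @param x Path to a YAML file, or a list with the fields above.
#' @return A validated list of class `run_config` with defaults filled in.
#' @export
validate_run_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort_config(sprintf("config file not found: %s", x))
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) abort_config("config must be a list or a YAML file path")
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk_file <- function(path, what) {
    if (is.null(path)) return(invisible())
    chk(is.character(path) && length(path) == 1 && file.exists(path),
        sprintf("%s: file not found (%s)", what, paste(path, collapse = ",")))
  }
  defaults <- list(alpha = 0.05, pseudocount = 1, enrichment_threshold = 0.05,
                   top_k = 20, min_samples = 8, pathways = NULL)
  for (f in names(defaults)) x[[f]] <- x[[f]] %||% defaults[[f]]
  chk(is.character(x$out_dir %||% "") && length(x$out_dir %||% "") == 1 &&
        nzchar(x$out_dir %||% ""), "out_dir: required")
  chk(is_prob(x$alpha) && x$alpha > 0 && x$alpha < 1,
      "alpha: must be in (0, 1)")
  chk(is.numeric(x$pseudocount) && length(x$pseudocount) == 1 &&
        x$pseudocount > 0, "pseudocount: must be positive")
  chk(is_prob(x$enrichment_threshold) && x$enrichment_threshold > 0 &&
        x$enrichment_threshold < 1, "enrichment_threshold: must be in (0, 1)")
  chk(is_count(x$top_k, 1), "top_k: must be a positive integer")
  chk(is_count(x$min_samples, 3), "min_samples: must be an integer >= 3")
  chk(length(x$cohorts %||% list()) >= 1, "cohorts: at least one required")
  for (i in seq_along(x$cohorts)) {
    co <- x$cohorts[[i]]
    chk(is.character(co$id %||% "") && nzchar(co$id %||% ""),
        sprintf("cohorts[%d]: id required", i))
    chk_file(co$expression, sprintf("cohorts[%d]$expression", i))
    chk(!is.null(co$expression), sprintf("cohorts[%d]: expression required", i))
    chk_file(co$pairs, sprintf("cohorts[%d]$pairs", i))
    chk(!is.null(co$pairs), sprintf("cohorts[%d]: pairs required", i))
    chk_file(co$cnv, sprintf("cohorts[%d]$cnv", i))
    chk_file(co$methylation, sprintf("cohorts[%d]$methylation", i))
  }
  ids <- vapply(x$cohorts, function(co) co$id %||% "", character(1))
  chk(!anyDuplicated(ids), "cohorts: ids must be unique")
  chk(!is.null(x$gene_sets$categories), "gene_sets$categories: required")
  chk_file(x$gene_sets$categories, "gene_sets$categories")
  chk_file(x$gene_sets$tissues, "gene_sets$tissues")
  chk_file(x$gene_sets$pathways, "gene_sets$pathways")
  chk_file(x$tissue_map, "tissue_map")
  chk_file(x$network, "network")
  if (length(problems) > 0) {
    abort_config(paste(c("invalid run config:", problems), collapse = "\n- "))
  }
  structure(x, class = "run_config")
}

stage_hash <- function(params, inputs) {
  digests <- vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
  rlang::hash(list(params = params, digests = digests))
}

stage_cached <- function(cache_dir, stage, hash, outputs) {
  hf <- file.path(cache_dir, paste0(stage, ".hash"))
  file.exists(hf) && identical(readLines(hf, warn = FALSE), hash) &&
    all(file.exists(outputs))
}

stage_mark <- function(cache_dir, stage, hash) {
  writeLines(hash, file.path(cache_dir, paste0(stage, ".hash")))
}

#' Run the full dysregulation pipeline from a configuration
#'
#' Executes, per cohort, differential expression, then category enrichment
#' and the tissue-specific analysis, the RBP cascade procedure (when a
#' network is configured), copy-number / methylation attribution (when the
#' matrices are configured), and finally pathway-restricted clustering of
#' the cohorts.  Stages are cached: a stage is skipped when its outputs
#' exist and the hash of its parameters and input files is unchanged.
#' Output files are written atomically and deterministically, so identical
#' inputs and config give byte-identical outputs.  A machine-readable
#' `run_report.json` summarises every stage; each reported count is
#' recomputable from the stage's output files.
#'
#' @param config A [validate_run_config()] result, config list, or YAML path.
#' @param force Recompute all stages, ignoring the cache.
#' @return Invisibly, the run report (a list, also written as JSON).
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_run_config(config)
  out <- cfg$out_dir
  cache <- file.path(out, ".cache")
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("pandys")),
    parameters = cfg[c("alpha", "pseudocount", "enrichment_threshold",
                       "top_k", "min_samples")],
    config_hash = rlang::hash(unclass(cfg)),
    stages = list(), cohorts = list())
  note <- function(stage, status, detail = NULL) {
    report$stages[[stage]] <<- c(list(status = status), detail)
  }

  catalog <- read_gmt(cfg$gene_sets$categories, "category")
  if (!is.null(cfg$gene_sets$tissues)) {
    tis <- read_gmt(cfg$gene_sets$tissues, "tissue")
    if (!is.null(cfg$tissue_map)) {
      tis <- set_tissue_cohorts(tis, read_tissue_map(cfg$tissue_map))
    }
    catalog <- catalog_bind(catalog, tis)
  }
  if (!is.null(cfg$gene_sets$pathways)) {
    catalog <- catalog_bind(catalog, read_gmt(cfg$gene_sets$pathways, "pathway"))
  }
  network <- if (!is.null(cfg$network)) read_network(cfg$network)

  ids <- vapply(cfg$cohorts, `[[`, character(1), "id")
  de_tables <- list()

  # ---- stage: differential expression ----
  for (co in cfg$cohorts) {
    stage <- paste0("de_", co$id)
    out_de <- file.path(out, paste0("de_", co$id, ".tsv"))
    h <- stage_hash(cfg[c("alpha", "pseudocount")], c(co$expression, co$pairs))
    if (!force && stage_cached(cache, stage, h, out_de)) {
      de_tables[[co$id]] <- read_de_table(out_de, alpha = cfg$alpha,
                                          pseudocount = cfg$pseudocount)
      note(stage, "cached")
    } else {
      res <- tryCatch({
        cohort <- read_expression(co$expression, co$pairs, cohort_id = co$id)
        de <- call_de(cohort, alpha = cfg$alpha, pseudocount = cfg$pseudocount)
        write_de_table(de, out_de)
        stage_mark(cache, stage, h)
        de_tables[[co$id]] <- de
        note(stage, "ok")
        TRUE
      }, error = function(e) {
        note(stage, "failed", list(error = conditionMessage(e)))
        FALSE
      })
    }
    if (co$id %in% names(de_tables)) {
      report$cohorts[[co$id]] <-
        list(n_genes = nrow(de_tables[[co$id]]),
             n_de = sum(de_tables[[co$id]]$is_de))
    }
  }

  # ---- stage: enrichment + tissue ----
  if (length(de_tables) > 0) {
    inputs <- file.path(out, paste0("de_", names(de_tables), ".tsv"))
    h <- stage_hash(cfg["enrichment_threshold"],
                    c(inputs, cfg$gene_sets$categories,
                      cfg$gene_sets$tissues %||% character(),
                      cfg$tissue_map %||% character()))
    out_enr <- file.path(out, "enrichment.tsv")
    out_tis <- file.path(out, "tissue.tsv")
    if (!force && stage_cached(cache, "enrichment", h, out_enr)) {
      note("enrichment", "cached")
      enr <- readr::read_tsv(out_enr, show_col_types = FALSE, progress = FALSE)
      report$stages$enrichment$n_enriched <- sum(enr$direction == "enriched")
    } else {
      tryCatch({
        enr <- enrichment_matrix(de_tables, catalog,
                                 threshold = cfg$enrichment_threshold)
        write_atomic(out_enr, function(p)
          readr::write_tsv(as_tibble(enr), p, progress = FALSE))
        tis_reports <- purrr::compact(purrr::map(de_tables, function(de) {
          tryCatch(suppressWarnings(tissue_specificity(
            de, catalog, threshold = cfg$enrichment_threshold)),
            error = function(e) NULL)
        }))
        if (length(tis_reports) > 0) {
          write_atomic(out_tis, function(p)
            readr::write_tsv(bind_rows(tis_reports), p, progress = FALSE))
        }
        stage_mark(cache, "enrichment", h)
        note("enrichment", "ok",
             list(n_enriched = sum(enr$direction == "enriched")))
      }, error = function(e) {
        note("enrichment", "failed", list(error = conditionMessage(e)))
      })
    }
  }

  # ---- stage: RBP cascade ----
  if (!is.null(network)) {
    for (cid in names(de_tables)) {
      stage <- paste0("cascade_", cid)
      outs <- file.path(out, paste0("cascade_", cid,
                                    c("_rbps.tsv", "_edges.tsv", "_nodes.tsv")))
      h <- stage_hash(cfg[c("top_k", "enrichment_threshold")],
                      c(file.path(out, paste0("de_", cid, ".tsv")),
                        cfg$network, cfg$gene_sets$categories))
      if (!force && stage_cached(cache, stage, h, outs[1])) {
        note(stage, "cached")
        next
      }
      tryCatch({
        casc <- suppressWarnings(cascade_select(
          de_tables[[cid]], catalog, network, top_k = cfg$top_k,
          threshold = cfg$enrichment_threshold))
        write_atomic(outs[1], function(p)
          readr::write_tsv(casc$rbp_stats, p, progress = FALSE))
        write_atomic(outs[2], function(p)
          readr::write_tsv(casc$subnetwork$edges, p, progress = FALSE))
        write_atomic(outs[3], function(p)
          readr::write_tsv(casc$nodes, p, progress = FALSE))
        stage_mark(cache, stage, h)
        note(stage, "ok", list(n_selected = sum(casc$rbp_stats$selected)))
        report$cohorts[[cid]]$n_cascade_rbps <- sum(casc$rbp_stats$selected)
      }, error = function(e) {
        note(stage, "failed", list(error = conditionMessage(e)))
      })
    }
  }

  # ---- stage: attribution ----
  for (co in cfg$cohorts) {
    for (assay in c("cnv", "methylation")) {
      if (is.null(co[[assay]]) || !co$id %in% names(de_tables)) next
      stage <- paste0("attribution_", co$id, "_", assay)
      out_att <- file.path(out, paste0(stage, ".tsv"))
      h <- stage_hash(cfg[c("min_samples", "pseudocount")],
                      c(co$expression, co$pairs, co[[assay]],
                        file.path(out, paste0("de_", co$id, ".tsv"))))
      if (!force && stage_cached(cache, stage, h, out_att)) {
        note(stage, "cached")
        next
      }
      tryCatch({
        cohort <- read_expression(co$expression, co$pairs, cohort_id = co$id)
        att <- per_gene_attribution(
          cohort, read_molecular(co[[assay]], assay), de_tables[[co$id]],
          catalog, pseudocount = cfg$pseudocount,
          min_samples = cfg$min_samples)
        cmp <- tryCatch(compare_groups(att), error = function(e) NULL)
        write_atomic(out_att, function(p)
          readr::write_tsv(att$rows, p, progress = FALSE))
        stage_mark(cache, stage, h)
        note(stage, "ok",
             if (!is.null(cmp)) list(wilcoxon_p = cmp$p_value))
        if (!is.null(cmp)) {
          report$cohorts[[co$id]][[paste0(assay, "_wilcoxon_p")]] <- cmp$p_value
        }
      }, error = function(e) {
        note(stage, "failed", list(error = conditionMessage(e)))
      })
    }
  }

  # ---- stage: pathway clustering ----
  if (length(de_tables) >= 2) {
    h <- stage_hash(cfg["pathways"],
                    c(file.path(out, paste0("de_", names(de_tables), ".tsv")),
                      cfg$gene_sets$pathways %||% character()))
    out_nwk <- file.path(out, "dendrogram_all_genes.nwk")
    if (!force && stage_cached(cache, "clustering", h, out_nwk)) {
      note("clustering", "cached")
    } else {
      tryCatch({
        panel <- suppressWarnings(
          pathway_panel(de_tables, catalog, pathways = cfg$pathways))
        for (nm in names(panel)) {
          dd <- panel[[nm]]
          write_atomic(file.path(out, paste0("distance_", nm, ".tsv")),
                       function(p) {
                         tab <- dplyr::bind_cols(
                           tibble(cohort_id = rownames(dd$dist)),
                           as_tibble(dd$dist))
                         readr::write_tsv(tab, p, progress = FALSE)
                       })
          write_atomic(file.path(out, paste0("dendrogram_", nm, ".nwk")),
                       function(p) writeLines(dd$newick, p))
        }
        stage_mark(cache, "clustering", h)
        note("clustering", "ok", list(n_dendrograms = length(panel)))
      }, error = function(e) {
        note("clustering", "failed", list(error = conditionMessage(e)))
      })
    }
  }

  write_atomic(file.path(out, "run_report.json"), function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(report)
}
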