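#' Configuration for the synthetic multi-cohort generator
#'
#' The generator plants, with recorded truth, every signal the analysis
#' stages look for: category-specific differential-expression probability
#' and effect size, hub RBPs whose PPI neighbors are loaded with DE and
#' cancer-related genes, copy-number profiles coupled to expression change
#' for a fraction of DE RBPs (methylation deliberately uncoupled),
#' under-expressed tissue-specific gene sets, and pathway-restricted
#' fold-change correlation between designated cohort pairs.
#'
#' Expression follows a log-normal model: for gene g and pair i the normal
#' value is `exp(mu_g + e)` and the tumor value `exp(mu_g + delta_g*ln2 + e')`
#' with `mu_g ~ N(baseline_log_mean, baseline_log_sd)`, independent noise
#' `e, e' ~ N(0, noise_sd)`, and `delta_g` the planted log2 effect: 0 unless
#' the gene is DE in that cohort, else `s * e` with random sign and
#' `e ~ Exponential(mean = effect_scale[category])`.  Planted fractions
#' (tissue under-expression, hub neighbor composition, CNV coupling) are
#' exact quotas; DE membership is Bernoulli per category.
#'
#' @param n_cohorts Number of cohorts (>= 2).
#' @param cohort_ids Cohort labels (default `C01`, `C02`, ...).
#' @param n_genes Genes per cohort (>= 100; all cohorts share the universe).
#' @param n_pairs Tumor/normal pairs per cohort (>= 10).
#' @param category_sizes Named integer vector of gene-category sizes;
#'   remaining genes form the implicit `other` background.
#' @param de_prob Per-category DE probability (must cover every category
#'   plus `other`).
#' @param effect_scale Per-category mean |log2 effect| of DE genes
#'   (default ordering allOnco > TF > lncRNA > RBP).
#' @param baseline_log_mean,baseline_log_sd Natural-log baseline abundance.
#' @param noise_sd Natural-log residual noise.
#' @param n_hub_rbps Number of designated DE-RBP hubs.
#' @param hub_neighbor_count Neighbors wired to each hub.
#' @param hub_onco_frac,hub_de_frac Quota fractions of each hub's neighbors
#'   that are cancer-related and forced DE, respectively.
#' @param hub_effect_min Minimum planted |log2 effect| for hubs, so that
#'   hubs land in the top of the fold-change ranking even after the
#'   pseudocount shrinks observed fold changes of low-abundance genes.
#' @param background_degree Mean degree of the background random graph.
#' @param cnv_coupled_frac Quota fraction of planted-DE RBPs whose
#'   copy-number profile tracks their expression change.
#' @param cnv_rho_target Population Spearman correlation for coupled genes.
#' @param cnv_noise_sd Residual sd of copy-number values.
#' @param tissue_set_size Tissue-specific genes planted DE per cohort
#'   (0 disables the layer).
#' @param tissue_under_frac Quota fraction of tissue genes planted with
#'   negative sign.
#' @param tissue_effect_scale Mean |log2 effect| of tissue genes.
#' @param similar_cohort_pairs List of cohort-id pairs that share pathway
#'   effects; defaults to the first two cohorts.  Pair i is planted in the
#'   i-th pathway of `pathway_sizes`.  `list()` disables the layer.
#' @param pathway_sizes Named integer vector of pathway set sizes.
#' @param pathway_noise_sd Cohort-specific perturbation added to the shared
#'   pathway effect.
#' @param methylation_shape1,methylation_shape2 Beta parameters for the
#'   (uncoupled) methylation values.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(
    n_cohorts = 4, cohort_ids = NULL, n_genes = 5000, n_pairs = 30,
    category_sizes = c(allOnco = 300, TF = 300, RBP = 300, lncRNA = 100,
                       Splic = 30, LDel = 30),
    de_prob = c(allOnco = 0.3, TF = 0.1, RBP = 0.3, lncRNA = 0.03,
                Splic = 0.1, LDel = 0.1, other = 0.1),
    effect_scale = c(allOnco = 3, TF = 2, RBP = 1, lncRNA = 1.5,
                     Splic = 1.5, LDel = 1.5, other = 1.5),
    baseline_log_mean = 5, baseline_log_sd = 1, noise_sd = 0.2,
    n_hub_rbps = 4, hub_neighbor_count = 30, hub_onco_frac = 0.5,
    hub_de_frac = 0.8, hub_effect_min = 3, background_degree = 6,
    cnv_coupled_frac = 0.5, cnv_rho_target = 0.6, cnv_noise_sd = 1,
    tissue_set_size = 400, tissue_under_frac = 0.8,
    tissue_effect_scale = 1.5,
    similar_cohort_pairs = NULL,
    pathway_sizes = c(cell_cycle = 100, p53_signaling = 100),
    pathway_noise_sd = 0.2,
    methylation_shape1 = 2, methylation_shape2 = 5,
    seed = 1) {
  cfg <- list(
    n_cohorts = n_cohorts,
    cohort_ids = cohort_ids %||% sprintf("C%02d", seq_len(n_cohorts)),
    n_genes = n_genes, n_pairs = n_pairs,
    category_sizes = category_sizes, de_prob = de_prob,
    effect_scale = effect_scale,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    noise_sd = noise_sd,
    n_hub_rbps = n_hub_rbps, hub_neighbor_count = hub_neighbor_count,
    hub_onco_frac = hub_onco_frac, hub_de_frac = hub_de_frac,
    hub_effect_min = hub_effect_min, background_degree = background_degree,
    cnv_coupled_frac = cnv_coupled_frac, cnv_rho_target = cnv_rho_target,
    cnv_noise_sd = cnv_noise_sd,
    tissue_set_size = tissue_set_size, tissue_under_frac = tissue_under_frac,
    tissue_effect_scale = tissue_effect_scale,
    similar_cohort_pairs = similar_cohort_pairs %||%
      (if (n_cohorts >= 2 && length(pathway_sizes) >= 1) {
        list(c(1, 2))
      } else list()),
    pathway_sizes = pathway_sizes, pathway_noise_sd = pathway_noise_sd,
    methylation_shape1 = methylation_shape1,
    methylation_shape2 = methylation_shape2,
    seed = seed
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(is_count(cfg$n_cohorts, 2), "n_cohorts must be an integer >= 2")
  chk(is_count(cfg$n_genes, 100), "n_genes must be an integer >= 100")
  chk(is_count(cfg$n_pairs, 10), "n_pairs must be an integer >= 10")
  chk(length(cfg$cohort_ids) == cfg$n_cohorts,
      "cohort_ids must have length n_cohorts")
  chk(sum(cfg$category_sizes) <= cfg$n_genes,
      "category sizes must sum to at most n_genes")
  cats <- c(names(cfg$category_sizes), "other")
  chk(all(cats %in% names(cfg$de_prob)),
      "de_prob must cover every category plus 'other'")
  chk(all(cats %in% names(cfg$effect_scale)),
      "effect_scale must cover every category plus 'other'")
  chk(all(cfg$de_prob >= 0 & cfg$de_prob <= 1), "de_prob values must be in [0, 1]")
  chk(all(cfg$effect_scale > 0), "effect_scale values must be positive")
  chk(cfg$noise_sd > 0, "noise_sd must be positive")
  chk(cfg$baseline_log_sd >= 0, "baseline_log_sd must be non-negative")
  for (f in c("hub_onco_frac", "hub_de_frac", "cnv_coupled_frac",
              "tissue_under_frac")) {
    chk(is_prob(cfg[[f]]), sprintf("%s must be in [0, 1]", f))
  }
  chk(cfg$cnv_rho_target > 0 && cfg$cnv_rho_target < 1,
      "cnv_rho_target must be in (0, 1)")
  chk(cfg$hub_neighbor_count <= cfg$n_genes - 1,
      "hub_neighbor_count must be at most n_genes - 1")
  if ("RBP" %in% names(cfg$category_sizes)) {
    chk(cfg$n_hub_rbps <= cfg$category_sizes[["RBP"]],
        "n_hub_rbps exceeds the RBP category size")
  } else {
    chk(cfg$n_hub_rbps == 0, "hub RBPs require an RBP category")
  }
  n_other <- cfg$n_genes - sum(cfg$category_sizes)
  chk(cfg$tissue_set_size * cfg$n_cohorts <= n_other,
      "tissue sets (disjoint per cohort) exceed the background gene pool")
  chk(length(cfg$similar_cohort_pairs) <= length(cfg$pathway_sizes),
      "need one pathway per similar cohort pair")
  for (p in cfg$similar_cohort_pairs) {
    ok <- length(p) == 2 &&
      all(p %in% cfg$cohort_ids | p %in% seq_len(cfg$n_cohorts))
    chk(ok, "each similar_cohort_pair must name two cohorts")
  }
  chk(is_count(cfg$seed) || is_count(-cfg$seed), "seed must be an integer")
  if (length(problems) > 0) {
    abort_config(paste(c("invalid simulation config:", problems),
                       collapse = "\n- "))
  }
  cfg
}

# linear index over unordered pairs (a < b), ordered by a then b
index_to_pair <- function(idx, n) {
  cs <- cumsum((n - 1):1)
  a <- findInterval(idx - 1, c(0, cs))
  b <- a + (idx - c(0, cs)[a])
  cbind(a, b)
}

sample_background_edges <- function(n, mean_degree) {
  total <- choose(n, 2)
  m <- rbinom(1, total, min(1, mean_degree / (n - 1)))
  if (m == 0) return(cbind(integer(), integer()))
  index_to_pair(sort(sample(total, m)), n)
}

#' Generate a synthetic multi-cohort dataset with planted signals
#'
#' See [sim_config()] for the generative model.  All randomness flows from
#' the single config seed; the same config always yields identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `cohorts` (named list
#'   of [paired_cohort()]), `catalog` ([gene_catalog()] with category,
#'   tissue and pathway sets), `network` ([ppi_network()]), `molecular`
#'   (per cohort, a list with `cnv` and `methylation`
#'   [molecular_matrix()]s), and `truth` (the planted-parameter ledger,
#'   class `truth_ledger`, consumed by tests).
#' @export
generate <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- cfg$cohort_ids
  genes <- sprintf("G%05d", seq_len(n))
  # contiguous category blocks; remaining genes are background "other"
  category <- rep("other", n)
  stop_at <- cumsum(cfg$category_sizes)
  start_at <- c(1, head(stop_at, -1) + 1)
  for (i in seq_along(cfg$category_sizes)) {
    category[start_at[i]:stop_at[i]] <- names(cfg$category_sizes)[i]
  }
  sets <- lapply(setNames(names(cfg$category_sizes),
                          names(cfg$category_sizes)),
                 function(cn) genes[category == cn])
  other_pool <- genes[category == "other"]

  # ---- shared structure: hubs, network, tissue sets, pathways ----
  rbp_genes <- sets[["RBP"]] %||% character()
  hubs <- if (cfg$n_hub_rbps > 0) sort(sample(rbp_genes, cfg$n_hub_rbps)) else character()
  onco_genes <- sets[["allOnco"]] %||% character()

  bg <- sample_background_edges(n, cfg$background_degree)
  edge_from <- genes[bg[, 1]]
  edge_to <- genes[bg[, 2]]
  hub_neighbors <- list()
  hub_forced_de <- list()
  for (h in hubs) {
    cnt <- cfg$hub_neighbor_count
    n_onco <- round(cfg$hub_onco_frac * cnt)
    nb_onco <- sample(setdiff(onco_genes, h), n_onco)
    nb_rest <- sample(setdiff(genes, c(h, onco_genes)), cnt - n_onco)
    nb <- c(nb_onco, nb_rest)  # onco first so the DE quota covers them
    hub_neighbors[[h]] <- nb
    hub_forced_de[[h]] <- nb[seq_len(round(cfg$hub_de_frac * cnt))]
    edge_from <- c(edge_from, rep(h, cnt))
    edge_to <- c(edge_to, nb)
  }
  network <- ppi_network(data.frame(from = edge_from, to = edge_to),
                         nodes = genes)

  tissue_sets <- list()
  if (cfg$tissue_set_size > 0) {
    pool <- sample(other_pool)  # disjoint draws across cohorts
    for (i in seq_along(ids)) {
      idx <- ((i - 1) * cfg$tissue_set_size + 1):(i * cfg$tissue_set_size)
      tissue_sets[[paste0("tissue_", ids[i])]] <- sort(pool[idx])
    }
  }
  tissue_map <- setNames(ids[seq_along(tissue_sets)], names(tissue_sets))

  # hubs keep their own planted effects: pathways draw from the other genes
  pathway_sets <- lapply(setNames(names(cfg$pathway_sizes),
                                  names(cfg$pathway_sizes)),
                         function(pn) sort(sample(setdiff(genes, hubs),
                                                  cfg$pathway_sizes[[pn]])))

  sim_pairs <- lapply(cfg$similar_cohort_pairs, function(p) {
    if (is.numeric(p)) ids[p] else as.character(p)
  })
  pair_pathway <- names(cfg$pathway_sizes)[seq_along(sim_pairs)]
  # shared pathway effects, one draw per pair
  shared_eff <- lapply(seq_along(sim_pairs), function(i) {
    members <- pathway_sets[[pair_pathway[i]]]
    scl <- cfg$effect_scale[category[match(members, genes)]]
    scl[is.na(scl)] <- cfg$effect_scale[["other"]]
    setNames(sample(c(-1, 1), length(members), TRUE) * rexp(length(members), 1 / scl),
             members)
  })

  catalog <- gene_catalog(
    sets = c(sets, tissue_sets, pathway_sets),
    kind = setNames(c(rep("category", length(sets)),
                      rep("tissue", length(tissue_sets)),
                      rep("pathway", length(pathway_sets))),
                    c(names(sets), names(tissue_sets), names(pathway_sets))),
    universe = genes, tissue_to_cohort = tissue_map
  )

  # ---- per-cohort expression, CNV, methylation ----
  sd_d <- cfg$noise_sd * sqrt(2) / log(2)  # sd of per-pair log2 change
  r_star <- 2 * sin(pi * cfg$cnv_rho_target / 6)
  slope <- r_star / sqrt(1 - r_star^2) * cfg$cnv_noise_sd / sd_d

  cohorts <- list(); molecular <- list()
  effects_rows <- list(); coupled_rows <- list(); tissue_rows <- list()
  for (ci in seq_along(ids)) {
    cid <- ids[ci]
    de <- runif(n) < cfg$de_prob[category]
    scl <- cfg$effect_scale[category]
    eff <- ifelse(de, sample(c(-1, 1), n, TRUE) * rexp(n, 1 / scl), 0)
    origin <- ifelse(de, "random", NA_character_)

    tset <- names(tissue_map)[tissue_map == cid]
    if (length(tset) == 1) {
      members <- tissue_sets[[tset]]
      idx <- match(members, genes)
      n_under <- round(cfg$tissue_under_frac * length(members))
      under <- rep(FALSE, length(members))
      under[sample(length(members), n_under)] <- TRUE
      de[idx] <- TRUE
      eff[idx] <- ifelse(under, -1, 1) *
        rexp(length(members), 1 / cfg$tissue_effect_scale)
      origin[idx] <- "tissue"
      tissue_rows[[cid]] <- tibble(cohort_id = cid, set_name = tset,
                                   gene = members, under = under)
    }

    forced_nb <- setdiff(unique(unlist(hub_forced_de)), hubs)
    if (length(forced_nb) > 0) {
      idx <- match(forced_nb, genes)
      fresh <- !de[idx]
      de[idx] <- TRUE
      scl_nb <- cfg$effect_scale[category[idx]]
      eff[idx[fresh]] <- sample(c(-1, 1), sum(fresh), TRUE) *
        rexp(sum(fresh), 1 / scl_nb[fresh])
      origin[idx] <- ifelse(fresh, "hub_neighbor", origin[idx])
    }

    if (length(hubs) > 0) {
      idx <- match(hubs, genes)
      de[idx] <- TRUE
      eff[idx] <- sample(c(-1, 1), length(hubs), TRUE) *
        (cfg$hub_effect_min + rexp(length(hubs), 2))
      origin[idx] <- "hub"
    }

    for (pi in seq_along(sim_pairs)) {
      if (cid %in% sim_pairs[[pi]]) {
        members <- names(shared_eff[[pi]])
        idx <- match(members, genes)
        de[idx] <- TRUE
        eff[idx] <- shared_eff[[pi]] +
          rnorm(length(members), 0, cfg$pathway_noise_sd)
        origin[idx] <- "pathway"
      }
    }

    mu <- rnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
    eps_n <- matrix(rnorm(n * cfg$n_pairs, 0, cfg$noise_sd), n)
    eps_t <- matrix(rnorm(n * cfg$n_pairs, 0, cfg$noise_sd), n)
    nor <- exp(mu + eps_n)
    tum <- exp(mu + eff * log(2) + eps_t)
    patients <- sprintf("%s_P%02d", cid, seq_len(cfg$n_pairs))
    expr <- cbind(tum, nor)
    rownames(expr) <- genes
    colnames(expr) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
    pairs <- tibble(patient_id = patients,
                    tumor_sample = paste0(patients, "_T"),
                    normal_sample = paste0(patients, "_N"))
    cohorts[[cid]] <- paired_cohort(expr, pairs, cid)

    # CNV: couple a quota of the planted-DE RBPs to the realized log2 change
    d_mat <- (log2(tum) - log2(nor))
    de_rbps <- genes[de & category == "RBP"]
    n_coup <- round(cfg$cnv_coupled_frac * length(de_rbps))
    coupled <- if (n_coup > 0) sort(sample(de_rbps, n_coup)) else character()
    cnv <- matrix(rnorm(n * cfg$n_pairs, 0, cfg$cnv_noise_sd), n,
                  dimnames = list(genes, patients))
    if (length(coupled) > 0) {
      idx <- match(coupled, genes)
      cnv[idx, ] <- slope * d_mat[idx, , drop = FALSE] +
        matrix(rnorm(length(idx) * cfg$n_pairs, 0, cfg$cnv_noise_sd),
               length(idx))
    }
    meth <- matrix(rbeta(n * cfg$n_pairs, cfg$methylation_shape1,
                         cfg$methylation_shape2), n,
                   dimnames = list(genes, patients))
    molecular[[cid]] <- list(cnv = molecular_matrix(cnv, "cnv"),
                             methylation = molecular_matrix(meth, "methylation"))
    coupled_rows[[cid]] <- tibble(cohort_id = cid, gene = coupled)
    effects_rows[[cid]] <- tibble(cohort_id = cid, gene = genes,
                                  category = category, de = de, effect = eff,
                                  origin = origin)
  }

  truth <- structure(
    list(gene_info = tibble(gene = genes, category = category),
         effects = bind_rows(effects_rows),
         hub_rbps = hubs,
         hub_neighbors = hub_neighbors,
         cnv_coupled = bind_rows(coupled_rows),
         tissue = bind_rows(tissue_rows),
         similar_pairs = purrr::map2(sim_pairs, pair_pathway[seq_along(sim_pairs)],
                                     function(p, pw) list(cohorts = p, pathway = pw)),
         seed = cfg$seed),
    class = "truth_ledger")

  structure(list(cohorts = cohorts, catalog = catalog, network = network,
                 molecular = molecular, truth = truth, config = cfg),
            class = "sim_result")
}

#' Null synthetic cohort with zero planted signal
#'
#' Log-normal expression with exchangeable tumor and normal columns; used by
#' type-I-error suites.
#'
#' @param n_genes,n_pairs Dimensions (`n_pairs >= 2`).
#' @param seed Integer seed.
#' @param baseline_log_mean,baseline_log_sd,noise_sd As in [sim_config()].
#' @param cohort_id Cohort label.
#' @return A [paired_cohort()].
#' @export
null_cohort <- function(n_genes, n_pairs, seed, baseline_log_mean = 5,
                        baseline_log_sd = 1, noise_sd = 0.2,
                        cohort_id = "NULL") {
  stopifnot(is_count(n_genes, 1), is_count(n_pairs, 2))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mu <- rnorm(n_genes, baseline_log_mean, baseline_log_sd)
  nor <- exp(mu + matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes))
  tum <- exp(mu + matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes))
  patients <- sprintf("%s_P%02d", cohort_id, seq_len(n_pairs))
  expr <- cbind(tum, nor)
  rownames(expr) <- genes
  colnames(expr) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  paired_cohort(expr,
                tibble(patient_id = patients,
                       tumor_sample = paste0(patients, "_T"),
                       normal_sample = paste0(patients, "_N")),
                cohort_id)
}

#' Write a generated dataset to disk in the pipeline's exchange formats
#'
#' Emits, under `dir`: per-cohort expression/pairing/CNV/methylation TSVs,
#' `categories.gmt`, `tissues.gmt`, `pathways.gmt`, `tissue_map.tsv`,
#' `network.tsv`, the planted-truth ledger as `truth.json`, and a ready
#' `run_config.yaml` pointing at all of them.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the written `run_config.yaml`.
#' @export
simulate_to_files <- function(config, dir) {
  sim <- generate(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  cohort_entries <- list()
  for (cid in names(sim$cohorts)) {
    write_expression(sim$cohorts[[cid]], p("expr_", cid, ".tsv"),
                     p("pairs_", cid, ".tsv"))
    write_molecular(sim$molecular[[cid]]$cnv, p("cnv_", cid, ".tsv"))
    write_molecular(sim$molecular[[cid]]$methylation, p("meth_", cid, ".tsv"))
    cohort_entries[[cid]] <- list(
      id = cid,
      expression = p("expr_", cid, ".tsv"), pairs = p("pairs_", cid, ".tsv"),
      cnv = p("cnv_", cid, ".tsv"), methylation = p("meth_", cid, ".tsv"))
  }
  cat_sets <- sets_of_kind(sim$catalog, "category")
  tis_sets <- sets_of_kind(sim$catalog, "tissue")
  pw_sets <- sets_of_kind(sim$catalog, "pathway")
  write_gmt(sim$catalog, p("categories.gmt"), sets = cat_sets)
  if (length(tis_sets) > 0) {
    write_gmt(sim$catalog, p("tissues.gmt"), sets = tis_sets)
    write_tissue_map(sim$catalog$tissue_to_cohort, p("tissue_map.tsv"))
  }
  if (length(pw_sets) > 0) write_gmt(sim$catalog, p("pathways.gmt"), sets = pw_sets)
  write_network(sim$network, p("network.tsv"))
  truth <- sim$truth
  truth_json <- list(
    gene_info = truth$gene_info, effects = truth$effects,
    hub_rbps = truth$hub_rbps, hub_neighbors = truth$hub_neighbors,
    cnv_coupled = truth$cnv_coupled, tissue = truth$tissue,
    similar_pairs = truth$similar_pairs, seed = truth$seed)
  write_atomic(p("truth.json"), function(path) {
    jsonlite::write_json(truth_json, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  run_cfg <- list(
    out_dir = file.path(dir, "results"),
    cohorts = unname(cohort_entries),
    gene_sets = c(list(categories = p("categories.gmt")),
                  if (length(tis_sets) > 0) list(tissues = p("tissues.gmt")),
                  if (length(pw_sets) > 0) list(pathways = p("pathways.gmt"))),
    network = p("network.tsv"))
  if (length(tis_sets) > 0) run_cfg$tissue_map <- p("tissue_map.tsv")
  write_atomic(p("run_config.yaml"), function(path) {
    yaml::write_yaml(run_cfg, path)
  })
  invisible(p("run_config.yaml"))
}
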