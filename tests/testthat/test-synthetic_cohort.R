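test_that("identical config and seed give identical output; seeds differ", {
  s1 <- generate(small_sim_config(seed = 5))
  s2 <- generate(small_sim_config(seed = 5))
  expect_identical(s1$cohorts[[1]]$expr, s2$cohorts[[1]]$expr)
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(s1$truth$effects, s2$truth$effects)
  expect_identical(s1$molecular[[1]]$cnv$values, s2$molecular[[1]]$cnv$values)
  s3 <- generate(small_sim_config(seed = 6))
  expect_false(identical(s1$cohorts[[1]]$expr, s3$cohorts[[1]]$expr))
})

test_that("a zero-signal config plants nothing", {
  cfg <- sim_config(
    n_cohorts = 2, n_genes = 200, n_pairs = 10,
    category_sizes = c(RBP = 20, allOnco = 20),
    de_prob = c(RBP = 0, allOnco = 0, other = 0),
    effect_scale = c(RBP = 1, allOnco = 1, other = 1),
    n_hub_rbps = 0, tissue_set_size = 0,
    similar_cohort_pairs = list(), seed = 2)
  sim <- generate(cfg)
  expect_false(any(sim$truth$effects$de))
  expect_true(all(sim$truth$effects$effect == 0))
  expect_length(sim$truth$hub_rbps, 0)
  expect_equal(nrow(sim$truth$cnv_coupled), 0)
})

test_that("realized DE fractions track the configured per-category probabilities", {
  cfg <- sim_config(
    n_cohorts = 2, n_genes = 5000, n_pairs = 10,
    category_sizes = c(RBP = 1000, allOnco = 500),
    de_prob = c(RBP = 0.3, allOnco = 0.1, other = 0.1),
    effect_scale = c(RBP = 1, allOnco = 1, other = 1),
    n_hub_rbps = 0, tissue_set_size = 0, similar_cohort_pairs = list(),
    seed = 3)
  truth <- generate(cfg)$truth
  eff1 <- truth$effects[truth$effects$cohort_id == "C01", ]
  for (cat_ in c("RBP", "allOnco", "other")) {
    rows <- eff1[eff1$category == cat_, ]
    p <- cfg$de_prob[[cat_]]
    sd3 <- 3 * sqrt(p * (1 - p) / nrow(rows))
    expect_lt(abs(mean(rows$de) - p), sd3)
  }
})

test_that("planted effects are recovered by the realized mean log2 change", {
  sim <- generate(small_sim_config(seed = 9, n_pairs = 30))
  co <- sim$cohorts[[1]]
  eff <- sim$truth$effects[sim$truth$effects$cohort_id == co$cohort_id, ]
  d <- rowMeans(log2(tumor_matrix(co)) - log2(normal_matrix(co)))
  planted <- eff$effect[match(names(d), eff$gene)]
  resid <- d - planted
  # per-gene standard error is noise_sd * sqrt(2) / (ln 2 * sqrt(n))
  se <- 0.2 * sqrt(2) / log(2) / sqrt(30)
  expect_lt(abs(mean(resid)), 3 * se / sqrt(length(resid)))
  expect_lt(sd(resid), se * 1.1)
  expect_gt(cor(d[eff$de], planted[eff$de]), 0.95)
})

test_that("planted quotas are exact: tissue signs, hub wiring, CNV coupling", {
  cfg <- small_sim_config(seed = 13)
  sim <- generate(cfg)
  tis <- sim$truth$tissue[sim$truth$tissue$cohort_id == "C01", ]
  expect_equal(nrow(tis), cfg$tissue_set_size)
  expect_equal(sum(tis$under), round(0.8 * cfg$tissue_set_size))

  for (h in sim$truth$hub_rbps) {
    nb <- sim$truth$hub_neighbors[[h]]
    expect_length(nb, cfg$hub_neighbor_count)
    expect_setequal(intersect(ppi_neighbors(sim$network, h), nb), nb)
    onco <- sim$catalog$sets$allOnco
    expect_equal(sum(nb %in% onco), round(0.5 * cfg$hub_neighbor_count))
    # forced-DE neighbors are DE in every cohort
    forced <- nb[seq_len(round(0.8 * cfg$hub_neighbor_count))]
    eff <- sim$truth$effects
    expect_true(all(eff$de[eff$gene %in% forced]))
  }

  eff1 <- sim$truth$effects[sim$truth$effects$cohort_id == "C01", ]
  de_rbps <- eff1$gene[eff1$de & eff1$category == "RBP"]
  coupled <- sim$truth$cnv_coupled$gene[sim$truth$cnv_coupled$cohort_id == "C01"]
  expect_equal(length(coupled), round(0.5 * length(de_rbps)))
  expect_true(all(coupled %in% de_rbps))
})

test_that("coupled CNV profiles correlate near target; uncoupled near zero", {
  cfg <- small_sim_config(seed = 17, n_pairs = 60)
  sim <- generate(cfg)
  co <- sim$cohorts[[1]]
  d <- pair_log2_change(co, pseudocount = 0)
  cnv <- sim$molecular[[1]]$cnv$values
  coupled <- sim$truth$cnv_coupled$gene[sim$truth$cnv_coupled$cohort_id == "C01"]
  rho_c <- vapply(coupled, function(g) spearman_rho(d[g, ], cnv[g, ]),
                  numeric(1))
  expect_lt(abs(mean(rho_c) - 0.6), 0.1)
  uncoupled <- setdiff(rownames(cnv), coupled)[1:50]
  rho_u <- vapply(uncoupled, function(g) spearman_rho(d[g, ], cnv[g, ]),
                  numeric(1))
  expect_lt(abs(mean(rho_u)), 0.1)
  # methylation is uncoupled and within [0, 1]
  meth <- sim$molecular[[1]]$methylation$values
  expect_true(all(meth >= 0 & meth <= 1))
  rho_m <- vapply(coupled, function(g) spearman_rho(d[g, ], meth[g, ]),
                  numeric(1))
  expect_lt(abs(mean(rho_m)), 0.1)
})

test_that("default effect scales order the categories' DE amplitudes", {
  ok <- 0
  for (s in 1:20) {
    cfg <- sim_config(
      n_cohorts = 2, n_genes = 2000, n_pairs = 10,
      category_sizes = c(allOnco = 300, TF = 300, RBP = 300, lncRNA = 300),
      de_prob = c(allOnco = 0.5, TF = 0.5, RBP = 0.5, lncRNA = 0.5,
                  other = 0.1),
      effect_scale = c(allOnco = 3, TF = 2, lncRNA = 1.5, RBP = 1,
                       other = 1.5),
      n_hub_rbps = 0, tissue_set_size = 0, similar_cohort_pairs = list(),
      seed = 100 + s)
    eff <- generate(cfg)$truth$effects
    eff <- eff[eff$cohort_id == "C01" & eff$de, ]
    means <- tapply(abs(eff$effect), eff$category, mean)
    if (means[["allOnco"]] > means[["TF"]] &&
        means[["TF"]] > means[["lncRNA"]] &&
        means[["lncRNA"]] > means[["RBP"]]) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("infeasible configurations are rejected with informative errors", {
  expect_error(sim_config(n_cohorts = 1), "n_cohorts",
               class = "pandys_config_error")
  expect_error(small_sim_config(hub_neighbor_count = 1000),
               "hub_neighbor_count", class = "pandys_config_error")
  expect_error(small_sim_config(tissue_set_size = 200),
               "tissue sets", class = "pandys_config_error")
  expect_error(
    sim_config(n_genes = 400, category_sizes = c(RBP = 500),
               de_prob = c(RBP = 1, other = 0),
               effect_scale = c(RBP = 1, other = 1)),
    "category sizes", class = "pandys_config_error")
})

test_that("null cohorts are signal-free and seed-sensitive", {
  c1 <- null_cohort(100, 10, seed = 1)
  c2 <- null_cohort(100, 10, seed = 2)
  expect_false(identical(c1$expr, c2$expr))
  d <- rowMeans(log2(tumor_matrix(c1) + 1) - log2(normal_matrix(c1) + 1))
  expect_lt(abs(mean(d)), 3 * 0.2 * sqrt(2) / log(2) / sqrt(10 * 100))
})
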