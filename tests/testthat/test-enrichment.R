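test_that("hypergeometric tails match hand-enumerable cases", {
  # N=10, K=5, n=4, k=4: only C(5,4)*C(5,0) of the C(10,4) draws qualify
  cell <- hypergeom_enrichment(10, 5, 4, 4)
  expect_equal(cell$p_enrich, 5 / 210, tolerance = 1e-12)
  # k at the lower edge of support
  cell0 <- hypergeom_enrichment(10, 5, 4, 0)
  expect_equal(cell0$p_enrich, 1)
  expect_equal(cell0$p_deplete, choose(5, 4) / choose(10, 4), tolerance = 1e-12)
  # symmetric configuration: p_enrich = (1 + P(X = 5)) / 2
  cell5 <- hypergeom_enrichment(20, 10, 10, 5)
  expect_equal(cell5$p_enrich, (1 + 252^2 / 184756) / 2, tolerance = 1e-12)
  expect_equal(cell5$p_enrich, 0.6718591, tolerance = 1e-6)
})

test_that("hypergeometric tails agree with exhaustive subset enumeration (small N)", {
  for (N in c(4, 6, 8)) {
    universe <- seq_len(N)
    for (K in 0:N) {
      for (n in 0:N) {
        draws <- utils::combn(N, n)
        if (n == 0) draws <- matrix(integer(), nrow = 0, ncol = 1)
        overlaps <- if (n == 0) 0 else colSums(draws <= K)
        for (k in max(0, n + K - N):min(K, n)) {
          cell <- hypergeom_enrichment(N, K, n, k)
          expect_equal(cell$p_enrich, mean(overlaps >= k), tolerance = 1e-12)
          expect_equal(cell$p_deplete, mean(overlaps <= k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric tails share the observed point and p_enrich decreases in k", {
  set.seed(2)
  for (i in 1:30) {
    N <- sample(10:2000, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(K, n)
    cells <- hypergeom_enrichment(N, K, n, ks)
    pmf <- stats::dhyper(ks, K, N - K, n)
    expect_equal(cells$p_enrich + cells$p_deplete - pmf,
                 rep(1, length(ks)), tolerance = 1e-9)
    expect_true(all(diff(cells$p_enrich) <= 1e-12))
  }
  expect_error(hypergeom_enrichment(10, 11, 2, 1), "K <= N")
  expect_error(hypergeom_enrichment(10, 5, 4, 5), "k <= min")
  expect_error(hypergeom_enrichment(10, 5, 4, -1), "k >=")
})

test_that("enrichment matrix counts overlaps on each cohort's own universe", {
  de <- manual_de_table(gene = sprintf("g%02d", 1:20),
                        log2fc = rep(1, 20),
                        p_adj = c(rep(0.001, 5), rep(1, 15)),
                        is_de = c(rep(TRUE, 5), rep(FALSE, 15)))
  catalog <- gene_catalog(list(same_as_de = sprintf("g%02d", 1:5),
                               disjoint = sprintf("g%02d", 6:15),
                               outside = c(sprintf("g%02d", 16:20), "zz")),
                          universe = c(sprintf("g%02d", 1:20), "zz"))
  m <- enrichment_matrix(de, catalog,
                         sets = c("same_as_de", "disjoint", "outside"))
  r1 <- m[m$set_name == "same_as_de", ]
  expect_equal(r1$k, 5); expect_equal(r1$K, 5); expect_equal(r1$n, 5)
  expect_equal(r1$p_enrich, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(r1$direction, "enriched")
  r2 <- m[m$set_name == "disjoint", ]
  expect_equal(r2$k, 0)
  expect_identical(r2$direction,
                   if (r2$p_deplete <= 0.05) "depleted" else "neither")
  # the catalog member missing from the cohort does not count toward K
  expect_equal(m$K[m$set_name == "outside"], 5)
  expect_error(enrichment_matrix(de, catalog, sets = "nope"), "unknown")
})

test_that("tissue report counts under-expressed DE tissue genes and tests them", {
  genes <- c(sprintf("t%02d", 1:3), sprintf("o%02d", 1:7))
  de <- manual_de_table(
    gene = genes,
    log2fc = c(-1, -2, 0.5, rnorm(7, 1)),
    is_de = c(TRUE, TRUE, TRUE, rep(TRUE, 4), rep(FALSE, 3)))
  catalog <- gene_catalog(list(tissue_X = sprintf("t%02d", 1:3)),
                          kind = "tissue", universe = genes,
                          tissue_to_cohort = c(tissue_X = "C01"))
  rep_ <- tissue_specificity(de, catalog)
  expect_equal(rep_$n_de_tissue, 3)
  expect_equal(rep_$n_under, 2)
  expect_equal(rep_$frac_under, 2 / 3)

  # ten DE tissue genes, all under-expressed: exact sign test 2 * (1/2)^10
  genes2 <- c(sprintf("t%02d", 1:10), sprintf("o%02d", 1:10))
  de2 <- manual_de_table(gene = genes2,
                         log2fc = c(rep(-1.5, 10), rep(1, 10)),
                         is_de = rep(TRUE, 20))
  catalog2 <- gene_catalog(list(tissue_X = sprintf("t%02d", 1:10)),
                           kind = "tissue", universe = genes2,
                           tissue_to_cohort = c(tissue_X = "C01"))
  rep2 <- tissue_specificity(de2, catalog2)
  expect_equal(rep2$sign_test_p, 2 * 0.5^10, tolerance = 1e-12)
  expect_lt(rep2$ranksum_p, 1e-4)

  # no matched tissue set: skipped with a warning, not an error
  catalog3 <- gene_catalog(list(tissue_X = "t01"), kind = "tissue",
                           universe = genes2,
                           tissue_to_cohort = c(tissue_X = "OTHER"))
  expect_warning(out <- tissue_specificity(de2, catalog3), "0 matched")
  expect_null(out)
})
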