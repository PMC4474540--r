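test_that("paired log2 fold change matches its definition", {
  expect_equal(paired_log2fc(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(paired_log2fc(c(3, 3), c(1, 1), pseudocount = 1), 1)
  expect_error(paired_log2fc(1:3, 1:2), "same length")
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    t_ <- rexp(n, 1 / 10); n_ <- rexp(n, 1 / 10)
    oracle <- mean(vapply(seq_len(n), function(j)
      log2((t_[j] + 1) / (n_[j] + 1)), numeric(1)))
    expect_equal(paired_log2fc(t_, n_), oracle, tolerance = 1e-12)
  }
})

test_that("paired t-test matches the closed form and stats::t.test", {
  res <- paired_t_test(c(1, 2, 3), c(0, 0, 0))  # differences (1, 2, 3)
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # for df = 2 the t CDF is F(t) = (1 + t / sqrt(t^2 + 2)) / 2
  t0 <- 2 * sqrt(3)
  expect_equal(res$p_value, 2 * (1 - (1 + t0 / sqrt(t0^2 + 2)) / 2),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.07417990, tolerance = 1e-7)

  expect_equal(paired_t_test(c(4, 4), c(4, 4)),
               list(t_stat = NA_real_, df = 1, p_value = 1))
  expect_error(paired_t_test(1, 1), "at least 2")

  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:25, 1)
    x <- rnorm(n); y <- rnorm(n)
    ref <- stats::t.test(x, y, paired = TRUE)
    res <- paired_t_test(x, y)
    expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment is the exact elementwise definition", {
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni(0.3), 0.3)
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bonferroni(p)
    expect_equal(adj, pmin(1, p * length(p)))
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0))  # order-preserving
  }
})

test_that("call_de matches per-gene t-tests on log2(x+1) and flags planted shifts", {
  co <- random_cohort(n_genes = 15, n_pairs = 6, seed = 21)
  de <- call_de(co)
  for (g in sample(cohort_genes(co), 5)) {
    ref <- stats::t.test(log2(tumor_matrix(co)[g, ] + 1),
                         log2(normal_matrix(co)[g, ] + 1), paired = TRUE)
    i <- match(g, de$gene)
    expect_equal(de$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(de$p_raw[i], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(de$p_adj, pmin(1, de$p_raw * nrow(de)))
  expect_identical(de$is_de, de$p_adj < 0.05)

  # a 4-fold planted shift at low noise must be called
  set.seed(1)
  expr <- matrix(rexp(20 * 20, 1 / 100) + 50, 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  expr <- cbind(expr, expr * matrix(rnorm(20 * 20, 1, 0.01), 20))
  expr[1, 21:40] <- expr[1, 1:20] * 4
  colnames(expr) <- c(paste0("p", 1:20, "N"), paste0("p", 1:20, "T"))
  co2 <- paired_cohort(expr,
                       tibble::tibble(patient_id = paste0("p", 1:20),
                                      tumor_sample = paste0("p", 1:20, "T"),
                                      normal_sample = paste0("p", 1:20, "N")),
                       "SHIFT")
  de2 <- call_de(co2)
  expect_true(de2$is_de[de2$gene == "g01"])
  expect_gt(de2$log2fc[de2$gene == "g01"], 1.8)

  # permuting gene order permutes the table identically
  perm <- sample(nrow(co$expr))
  co_p <- paired_cohort(co$expr[perm, ], co$pairs, co$cohort_id)
  de_p <- call_de(co_p)
  expect_equal(as.data.frame(de_p),
               as.data.frame(de[match(de_p$gene, de$gene), ]))
})

test_that("genes with identical tumor/normal vectors stay in the universe with p = 1", {
  expr <- matrix(5, 3, 4, dimnames = list(c("a", "b", "c"),
                                          c("x1T", "x1N", "x2T", "x2N")))
  expr[2, c(1, 3)] <- c(9, 11)
  co <- paired_cohort(expr,
                      tibble::tibble(patient_id = c("x1", "x2"),
                                     tumor_sample = c("x1T", "x2T"),
                                     normal_sample = c("x1N", "x2N")), "Z")
  de <- call_de(co)
  expect_equal(de$p_raw[de$gene == "a"], 1)
  expect_true(is.na(de$t_stat[de$gene == "a"]))
  expect_false(de$is_de[de$gene == "a"])
  expect_equal(nrow(de), 3)
})

test_that("amplitude profiles expose ECDFs and rank-sum comparisons", {
  de <- manual_de_table(gene = c("a", "b", "c", "d"),
                        log2fc = c(1, -2, 3, 0.5),
                        is_de = c(TRUE, TRUE, TRUE, FALSE))
  catalog <- gene_catalog(list(S1 = c("a", "b", "c"),
                               S2 = c("a", "b", "c"),
                               S3 = "d"),
                          universe = c("a", "b", "c", "d"))
  prof <- amplitude_profiles(de, catalog, sets = c("S1", "S2", "S3"))
  expect_equal(prof$ecdfs$S1(2), 2 / 3)
  expect_identical(prof$empty_sets, "S3")  # d is not DE
  cmp <- prof$comparisons
  p12 <- cmp$p_greater[cmp$set_a == "S1" & cmp$set_b == "S2"]
  expect_gt(p12, 0.4)  # identical sets: no detectable difference
  expect_error(amplitude_profiles(de, catalog, sets = "nope"), "unknown")
})
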