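test_that("expression round-trips through TSV, preserving order and values", {
  co <- tiny_cohort()
  ep <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(co, ep, pp)
  back <- read_expression(ep, pp, cohort_id = "TINY")
  expect_identical(cohort_genes(back), cohort_genes(co))
  expect_identical(back$expr, co$expr)
  expect_equal(n_pairs(back), 2)

  # bit-exact round trip on random full-precision matrices
  for (s in 1:20) {
    co <- random_cohort(n_genes = 8, n_pairs = 3, seed = s)
    write_expression(co, ep, pp)
    back <- read_expression(ep, pp)
    expect_identical(back$expr, co$expr)
    expect_identical(back$pairs, co$pairs)
  }
})

test_that("malformed expression inputs produce named format errors", {
  co <- tiny_cohort()
  ep <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(co, ep, pp)

  bad_pairs <- co$pairs
  bad_pairs$tumor_sample[1] <- "missing_col"
  readr::write_tsv(bad_pairs, pp)
  expect_error(read_expression(ep, pp), "missing_col",
               class = "pandys_format_error")

  # duplicate gene symbol named in the error
  lines <- readLines(ep)
  writeLines(c(lines, lines[2]), ep)
  readr::write_tsv(co$pairs, pp)
  expect_error(read_expression(ep, pp), "TP53",
               class = "pandys_format_error")

  expr <- co$expr; expr[2, 1] <- -1
  expect_error(paired_cohort(expr, co$pairs, "X"), "negative",
               class = "pandys_format_error")
})

test_that("GMT reading collapses duplicates, tags kinds, and round-trips", {
  gp <- withr::local_tempfile(fileext = ".gmt")
  writeLines("RBP\tna\tA\tB\tB", gp)
  frag <- read_gmt(gp, kind = "category")
  expect_identical(frag$sets$RBP, c("A", "B"))
  expect_identical(unname(frag$set_kind["RBP"]), "category")

  writeLines(character(), gp)
  expect_length(read_gmt(gp)$sets, 0)

  writeLines(c("ok\tna\tA", "short\tna"), gp)
  expect_error(read_gmt(gp), "line 2", class = "pandys_format_error")

  set.seed(7)
  for (i in 1:10) {
    sets <- lapply(setNames(1:3, paste0("set", 1:3)), function(j)
      sample(sprintf("G%02d", 1:30), sample(3:10, 1)))
    cat0 <- gene_catalog(sets, kind = "pathway")
    write_gmt(cat0, gp)
    expect_identical(read_gmt(gp, kind = "pathway")$sets, cat0$sets)
  }
})

test_that("network reading drops self-loops, collapses reversed edges, round-trips", {
  np <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), np)
  w <- testthat::capture_warning(read_network(np))
  expect_match(conditionMessage(w), "1 self-loop")
  net <- suppressWarnings(read_network(np))
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$from, "A")
  expect_identical(net$edges$to, "B")

  writeLines(character(), np)
  expect_equal(nrow(read_network(np)$edges), 0)

  writeLines("A\tB\tC", np)
  expect_error(read_network(np), "expected 2", class = "pandys_format_error")

  set.seed(11)
  for (i in 1:10) {
    nodes <- sprintf("N%02d", 1:15)
    e <- t(replicate(20, sample(nodes, 2)))
    net0 <- ppi_network(e)
    write_network(net0, np)
    expect_identical(read_network(np)$edges, net0$edges)
  }
})

test_that("universe restriction shrinks sets/edges, reports counts, is idempotent", {
  co <- random_cohort(n_genes = 10, n_pairs = 3)
  genes <- cohort_genes(co)
  catalog <- gene_catalog(list(inpart = c(genes[1:2], "ZZZ"),
                               gone = c("X1", "X2")),
                          universe = c(genes, "ZZZ", "X1", "X2"))
  net <- ppi_network(data.frame(from = c(genes[1], genes[2]),
                                to = c(genes[3], "ZZZ")))
  expect_warning(intersect_universe(co, catalog, net), "gone")
  rv <- suppressWarnings(intersect_universe(co, catalog, net))
  expect_identical(rv$catalog$sets$inpart, genes[1:2])
  expect_identical(rv$catalog$sets$gone, character(0))
  expect_equal(rv$retained$retained[rv$retained$set_name == "inpart"], 2L)
  expect_equal(nrow(rv$network$edges), 1)  # edge to ZZZ dropped
  expect_identical(rv$cohort$expr, co$expr)

  rv2 <- suppressWarnings(
    intersect_universe(rv$cohort, rv$catalog, rv$network))
  expect_identical(rv2$catalog$sets, rv$catalog$sets)
  expect_identical(rv2$network$edges, rv$network$edges)
})

test_that("an annotation set mostly absent from the matrix keeps only measured members", {
  # mirrors the situation where only 264 of 9227 annotated lncRNAs are
  # present in a standardized expression matrix
  all_lnc <- sprintf("LNC%04d", 1:9227)
  measured <- c(sprintf("GEN%04d", 1:200), all_lnc[1:264])
  expr <- matrix(1, length(measured), 4,
                 dimnames = list(measured, c("aT", "aN", "bT", "bN")))
  co <- paired_cohort(expr,
                      tibble::tibble(patient_id = c("a", "b"),
                                     tumor_sample = c("aT", "bT"),
                                     normal_sample = c("aN", "bN")), "X")
  catalog <- gene_catalog(list(lncRNA = all_lnc),
                          universe = union(all_lnc, measured))
  rv <- intersect_universe(co, catalog)
  expect_length(rv$catalog$sets$lncRNA, 264)
})
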