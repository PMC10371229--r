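test_that("the forced 4-gene running curve is exact", {
  r <- tibble::tibble(gene = c("a", "b", "c", "d"), metric = c(4, 3, 2, 1))
  res <- running_enrichment_score(r, "a", weight_exponent = 0)
  expect_equal(res$running$score, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(res$es, 1)
})

test_that("ES equals brute force for every 2-subset of a 6-gene universe", {
  genes <- letters[1:6]
  set.seed(20)
  metric <- sort(rnorm(6), decreasing = TRUE)
  r <- tibble::tibble(gene = genes, metric = metric)
  for (w in c(0, 1)) {
    for (pair in utils::combn(genes, 2, simplify = FALSE)) {
      expect_equal(running_enrichment_score(r, pair, w)$es,
                   oracle_wks(genes, metric, pair, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("reversing a ranking negates the ES at w = 0", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:40)
  set_g <- sample(genes, 8)
  expect_equal(running_enrichment_score(genes, set_g, 0)$es,
               -running_enrichment_score(rev(genes), set_g, 0)$es,
               tolerance = 1e-12)
})

test_that("a contiguous bottom block reaches the analytic extreme of -1 at w = 0", {
  genes <- sprintf("g%02d", 1:30)
  r <- tibble::tibble(gene = genes, metric = seq(30, 1))
  bottom <- genes[26:30]
  expect_equal(running_enrichment_score(r, bottom, 0)$es, -1, tolerance = 1e-12)
  top <- genes[1:5]
  expect_equal(running_enrichment_score(r, top, 0)$es, 1, tolerance = 1e-12)
})

test_that("ES is bounded and ignores genes outside the universe", {
  set.seed(22)
  for (i in 1:20) {
    genes <- sprintf("g%03d", 1:50)
    r <- tibble::tibble(gene = genes, metric = rnorm(50))
    s <- sample(genes, sample(2:20, 1))
    es <- running_enrichment_score(r, s, 1)$es
    expect_gte(es, -1)
    expect_lte(es, 1)
    expect_equal(running_enrichment_score(r, c(s, "not_a_gene"), 1)$es, es)
  }
})

test_that("degenerate sets are refused", {
  r <- tibble::tibble(gene = c("a", "b"), metric = c(2, 1))
  expect_error(running_enrichment_score(r, "zzz"), "disjoint")
  expect_error(running_enrichment_score(r, c("a", "b")), "universe")
})

test_that("ES agrees with an established GSEA implementation at w = 1", {
  library(fgsea)
  set.seed(23)
  stats <- sort(setNames(rnorm(100), sprintf("g%03d", 1:100)), decreasing = TRUE)
  r <- tibble::tibble(gene = names(stats), metric = unname(stats))
  for (i in 1:5) {
    s <- sample(names(stats), 12)
    ours <- running_enrichment_score(r, s, weight_exponent = 1)$es
    theirs <- fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% s),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("permutation p is extreme for a planted top block and honest for random sets", {
  genes <- sprintf("g%03d", 1:100)
  r <- tibble::tibble(gene = genes, metric = seq(100, 1))
  planted <- es_permutation_p(r, genes[1:10], weight_exponent = 0,
                              n_perm = 200, seed = 2)
  expect_equal(planted$p_value, 1 / 201)
  set.seed(24)
  random_p <- vapply(1:30, function(i) {
    es_permutation_p(r, sample(genes, 10), weight_exponent = 0,
                     n_perm = 100, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(random_p), 0.2)  # not systematically small under the null
  expect_error(es_permutation_p(r, genes[1:5], n_perm = 50), "at least 100")
})

test_that("connectivity averages per-cell-line ES and flags low coverage", {
  genes <- sprintf("g%02d", 1:20)
  one_line <- tibble::tibble(compound = "c1", cell_line = "A",
                             gene = genes, rank = 1:20)
  sig <- dplyr::bind_rows(
    one_line,
    dplyr::mutate(one_line, cell_line = "B"),
    dplyr::mutate(one_line, cell_line = "C")
  )
  q <- genes[16:20]
  single <- running_enrichment_score(genes, q, 0)$es
  conn <- connectivity_score(sig, q)
  expect_equal(conn$raw_score, single, tolerance = 1e-12)
  expect_equal(conn$n_cell_lines, 3L)
  # query genes absent from the universe: scored on the intersection
  conn2 <- connectivity_score(sig, c(q, sprintf("x%02d", 1:5)))
  expect_equal(conn2$coverage, 0.5)
})

test_that("tidy/glance/autoplot expose the enrichment result", {
  r <- tibble::tibble(gene = letters[1:6], metric = 6:1)
  res <- running_enrichment_score(r, c("a", "f"), 0)
  expect_identical(tidy(res), res$running)
  expect_equal(glance(res)$es, res$es)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("enrichment tables rank a planted set first with BH-adjusted p", {
  set.seed(25)
  genes <- sprintf("g%03d", 1:80)
  metric <- sort(rnorm(80), decreasing = TRUE)
  sets <- list(top = genes[1:10], random = sample(genes, 10))
  tab <- enrichment_table(tibble::tibble(gene = genes, metric = metric), sets,
                          n_perm = 200, seed = 3)
  expect_identical(tab$set[1], "top")
  expect_equal(tab$p_value[1], 1 / 201)
  expect_identical(tab$q_value, unname(p.adjust(tab$p_value, "BH")))
})
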