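test_that("a perfect linear relationship is recovered exactly", {
  set.seed(1)
  x <- rnorm(50)
  res <- fit_protein_trait_model(x, 2 * x + 5)
  expect_equal(res$effect, 2, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-30)
  expect_false(res$flagged)
})

test_that("null proteins give uniform p-values", {
  set.seed(2)
  n <- 400
  trait <- rnorm(n)
  p <- replicate(200, fit_protein_trait_model(rnorm(n), trait)$p_value)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("constant proteins are flagged and excluded from q-values", {
  res <- fit_protein_trait_model(rep(1, 30), rnorm(30))
  expect_true(res$flagged)
  expect_true(is.na(res$p_value))
})

test_that("complete cases only: missing protein values drop rows", {
  set.seed(3)
  x <- rnorm(40)
  y <- x + rnorm(40, 0, 0.1)
  x[1:10] <- NA
  res <- fit_protein_trait_model(x, y)
  expect_identical(res$n_used, 30L)
  res_oracle <- summary(lm(y[11:40] ~ x[11:40]))
  expect_equal(res$effect, unname(coef(res_oracle)[2, 1]), tolerance = 1e-12)
  expect_equal(res$p_value, unname(coef(res_oracle)[2, 4]), tolerance = 1e-12)
})

test_that("scan output is deterministic, ordered, and permutation-invariant", {
  cfg <- small_cfg(seed = 9)
  st <- simulate_study(cfg)
  ph <- phenotype_table(st$gtt, st$bodycomp)
  prot <- presence_filter(st$proteome)
  res1 <- run_association_scan(prot, ph, protein_info = st$protein_info)
  expect_identical(res1$protein_id, sort(res1$protein_id))
  # shuffling mouse rows of both tables leaves results identical
  set.seed(1)
  shuf <- sample(nrow(ph))
  res2 <- run_association_scan(
    dplyr::arrange(prot, match(mouse_id, ph$mouse_id[shuf])),
    ph[shuf, ], protein_info = st$protein_info
  )
  expect_equal(res1, res2)
  # duplicated protein column gives identical statistics
  dup <- dplyr::mutate(dplyr::filter(prot, protein_id == res1$protein_id[1]),
                       protein_id = "ZZZ_copy")
  res3 <- run_association_scan(dplyr::bind_rows(prot, dup), ph,
                               protein_info = NULL)
  expect_equal(
    res3[res3$protein_id == "ZZZ_copy", c("effect", "p_value", "n_used")],
    res3[res3$protein_id == res1$protein_id[1], c("effect", "p_value", "n_used")]
  )
})

test_that("misaligned mouse ids are rejected with the first mismatch named", {
  cfg <- small_cfg(seed = 4)
  st <- simulate_study(cfg)
  ph <- phenotype_table(st$gtt, st$bodycomp)
  ph$mouse_id[1] <- "mouse_999"
  expect_error(run_association_scan(presence_filter(st$proteome), ph),
               "misaligned.*mouse_")
})

test_that("adiposity confounding is flagged without the covariate and abolished with it", {
  cfg <- small_cfg(seed = 11, n_mice = 150, confound_strength = 1.2,
                   adiposity_effect = -0.8, missing_rate = 0)
  st <- simulate_study(cfg)
  ph <- phenotype_table(st$gtt, st$bodycomp)
  prot <- presence_filter(st$proteome)
  with_cov <- run_association_scan(prot, ph, covariates = "adiposity")
  without_cov <- run_association_scan(prot, ph, covariates = NULL)
  conf <- st$truth$confounded_proteins
  p_without <- without_cov$p_value[match(conf, without_cov$protein_id)]
  p_with <- with_cov$p_value[match(conf, with_cov$protein_id)]
  # confounded proteins look associated in the unadjusted model only
  expect_gt(median(-log10(p_without)), median(-log10(p_with)))
  expect_true(all(p_without < 0.05))
  ov <- consensus_overlap(with_cov, without_cov, q_threshold = 0.05)
  expect_true(all(ov$category[match(conf, ov$protein_id)] %in%
                    c("only_without", "neither")))
  expect_gt(sum(ov$category[match(conf, ov$protein_id)] == "only_without"), 0)
})

test_that("consensus overlap handles identical and disjoint significance", {
  a <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                      effect = c(-1, 1, 0.5), q_value = c(0.01, 0.2, 0.01))
  expect_true(all(consensus_overlap(a, a)$category %in% c("consensus", "neither")))
  b <- a
  b$q_value <- c(0.2, 0.01, 0.2)
  ov <- consensus_overlap(a, b)
  expect_false(any(ov$category == "consensus"))
  expect_setequal(ov$category[ov$protein_id %in% c("p1", "p3")], "only_with")
})
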