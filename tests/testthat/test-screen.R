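toy_plate <- function(mode, controls, compounds) {
  ctrl <- purrr::imap_dfr(controls, function(v, nm) {
    tibble::tibble(mode = mode, well_type = "control", control_type = nm,
                   compound = NA_character_, replicate = seq_along(v), value = v)
  })
  cmp <- purrr::imap_dfr(compounds, function(v, nm) {
    tibble::tibble(mode = mode, well_type = "compound", control_type = NA,
                   compound = nm, replicate = seq_along(v), value = v)
  })
  dplyr::bind_rows(ctrl, cmp)
}

test_that("basal-agonist hits use 50% of the insulin response, strictly", {
  plate <- toy_plate("basal_agonist",
                     list(basal = 5, insulin_100nM = 25),
                     list(hit = 16, boundary = 15, miss = 14))
  calls <- call_hits(plate)
  expect_equal(unique(calls$threshold), 15)
  expect_identical(calls$is_hit[match(c("hit", "boundary", "miss"), calls$compound)],
                   c(TRUE, FALSE, FALSE))
  # literal absolute rule: threshold = 0.5 * insulin100
  abs_calls <- call_hits(plate, basal_rule = "absolute")
  expect_equal(unique(abs_calls$threshold), 12.5)
})

test_that("reverser and sensitiser thresholds follow their difference rules", {
  rev_plate <- toy_plate("reverser",
                         list(basal = 5, insulin_100nM = 30, insulin_palmitate = 10),
                         list(boundary = 20, hit = 20.01))
  rev_calls <- call_hits(rev_plate)
  expect_equal(unique(rev_calls$threshold), 20)
  expect_identical(rev_calls$is_hit[match(c("boundary", "hit"), rev_calls$compound)],
                   c(FALSE, TRUE))
  sens_plate <- toy_plate("sensitiser",
                          list(basal = 5, insulin_1nM = 10, insulin_100nM = 30),
                          list(c1 = 21, c2 = 19))
  sens_calls <- call_hits(sens_plate)
  expect_equal(unique(sens_calls$threshold), 20)
  expect_identical(sens_calls$is_hit[match(c("c1", "c2"), sens_calls$compound)],
                   c(TRUE, FALSE))
})

test_that("ten-compound toy plate reproduces hand-computed calls", {
  responses <- setNames(c(10, 14.9, 15, 15.1, 20, 25, 30, 5, 16, 14.99),
                        paste0("cpd", 1:10))
  plate <- toy_plate("basal_agonist",
                     list(basal = c(5, 5), insulin_100nM = c(24, 26)),
                     as.list(responses))
  calls <- call_hits(plate)
  hand <- responses > 15
  expect_identical(calls$is_hit[match(names(responses), calls$compound)],
                   unname(hand))
})

test_that("missing controls and missing assay window are refused", {
  no_ctrl <- toy_plate("reverser", list(basal = 5, insulin_100nM = 30),
                       list(c1 = 10))
  expect_error(call_hits(no_ctrl), "insulin_palmitate")
  no_window <- toy_plate("basal_agonist",
                         list(basal = 25, insulin_100nM = 20), list(c1 = 10))
  expect_error(call_hits(no_window), "window")
})

test_that("overlap summary equals brute-force set arithmetic", {
  mk_hits <- function(mode, hits, all = paste0("c", 1:10)) {
    tibble::tibble(compound = all, mode = mode, response = 0, threshold = 0,
                   is_hit = all %in% hits)
  }
  h <- list(mk_hits("basal_agonist", c("c1", "c2", "c3")),
            mk_hits("sensitiser", c("c2", "c3", "c4")),
            mk_hits("reverser", c("c3", "c5")))
  ov <- overlap_summary(h)
  expect_equal(ov$count[ov$region == "basal_agonist"], 1)           # c1
  expect_equal(ov$count[ov$region == "basal_agonist&sensitiser"], 1) # c2
  expect_equal(ov$count[ov$region == "basal_agonist&sensitiser&reverser"], 1) # c3
  expect_equal(ov$count[ov$region == "reverser"], 1)                # c5
  # identical hit sets: everything in the triple overlap
  h2 <- list(mk_hits("basal_agonist", c("c1", "c2")),
             mk_hits("sensitiser", c("c1", "c2")),
             mk_hits("reverser", c("c1", "c2")))
  ov2 <- overlap_summary(h2)
  expect_equal(ov2$count[ov2$region == "basal_agonist&sensitiser&reverser"], 2)
  expect_equal(sum(ov2$count), 2)
})

test_that("z-scores follow the definitional contract", {
  expect_equal(zscore_column(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(30)
  x <- rnorm(50, 10, 4)
  z <- zscore_column(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z, (x - mean(x)) / sd(x), tolerance = 1e-14)
  # NA propagates, excluded from mean/SD
  x2 <- c(x, NA)
  z2 <- zscore_column(x2)
  expect_true(is.na(z2[51]))
  expect_equal(z2[1:50], z, tolerance = 1e-14)
  expect_error(zscore_column(rep(2, 5)), "zero")
  expect_error(zscore_column(1), "at least 2")
})

test_that("overall score reproduces the integration formula", {
  expect_equal(overall_score(1, 1, 1, 1), 2)
  expect_equal(overall_score(0, 0, 0, 0), 0)
  set.seed(31)
  zb <- rnorm(20); zs <- rnorm(20); zr <- rnorm(20); zc <- rnorm(20)
  expect_equal(overall_score(zb, zs, zr, zc), (zb + zs + zr) / 3 + zc,
               tolerance = 1e-15)
})

test_that("score matrix z-columns are normalised over the consensus set", {
  cfg <- small_cfg(seed = 33)
  st <- simulate_study(cfg)
  hits <- purrr::map(st$screen, call_hits)
  conn <- connectivity_score(st$signatures, st$truth$fingerprint_genes)
  scores <- build_score_matrix(hits, conn)
  for (col in c("z_bas", "z_sens", "z_rev", "z_cmap")) {
    expect_equal(mean(scores[[col]]), 0, tolerance = 1e-9)
    expect_equal(sd(scores[[col]]), 1, tolerance = 1e-9)
  }
  expect_equal(scores$overall,
               (scores$z_bas + scores$z_sens + scores$z_rev) / 3 + scores$z_cmap,
               tolerance = 1e-12)
  # stronger reversal (more negative raw score) means larger z_cmap
  o <- order(conn$raw_score[match(scores$compound, conn$compound)])
  expect_false(is.unsorted(rev(scores$z_cmap[o])))
})

test_that("ranking is deterministic and row-permutation invariant", {
  set.seed(32)
  scores <- tibble::tibble(
    compound = sprintf("c%02d", 1:15),
    z_bas = rnorm(15), z_sens = rnorm(15), z_rev = rnorm(15), z_cmap = rnorm(15)
  ) |>
    dplyr::mutate(overall = overall_score(z_bas, z_sens, z_rev, z_cmap))
  r1 <- rank_compounds(scores)
  r2 <- rank_compounds(scores[sample(15), ])
  expect_identical(r1, r2)
  expect_false(is.unsorted(rev(r1$overall)))
  # dominating compound ranks first
  scores$z_bas[3] <- scores$z_sens[3] <- scores$z_rev[3] <- scores$z_cmap[3] <- 10
  scores$overall <- overall_score(scores$z_bas, scores$z_sens,
                                  scores$z_rev, scores$z_cmap)
  expect_identical(rank_compounds(scores)$compound[1], "c03")
  # ties broken by z_cmap then compound id
  tied <- tibble::tibble(compound = c("b", "a"), z_bas = 0, z_sens = 0,
                         z_rev = c(3, 0), z_cmap = c(0, 1),
                         overall = c(1, 1))
  expect_identical(rank_compounds(tied)$compound, c("a", "b"))
})
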