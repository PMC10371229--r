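make_long <- function(values) {
  # values: mice x proteins matrix
  df <- as.data.frame.table(values, stringsAsFactors = FALSE)
  names(df) <- c("mouse_id", "protein_id", "value")
  tibble::as_tibble(df)
}

test_that("presence filter keeps the inclusive boundary and is idempotent", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("m", 1:4), paste0("p", 1:3)))
  m[1:2, 2] <- NA      # exactly 50% observed
  m[1:3, 3] <- NA      # 25% observed
  long <- make_long(m)
  kept <- presence_filter(long, 0.5)
  expect_setequal(unique(kept$protein_id), c("p1", "p2"))
  expect_identical(presence_filter(kept, 0.5), kept)
  # fully observed matrix is untouched
  full <- make_long(matrix(rnorm(12), 4, 3,
                           dimnames = list(paste0("m", 1:4), paste0("p", 1:3))))
  expect_identical(presence_filter(full), full)
})

test_that("presence filter agrees with a counting oracle on random missingness", {
  set.seed(7)
  vals <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("m%02d", 1:20), sprintf("p%02d", 1:10)))
  vals[runif(200) < 0.45] <- NA
  long <- make_long(vals)
  kept <- unique(presence_filter(long, 0.5)$protein_id)
  oracle <- colnames(vals)[colSums(!is.na(vals)) / nrow(vals) >= 0.5]
  expect_setequal(kept, oracle)
})

test_that("normalisation centres every mouse to the grand median", {
  set.seed(1)
  raw <- make_long(matrix(2^rnorm(60, 20, 2), 6, 10,
                          dimnames = list(paste0("m", 1:6), paste0("p", 1:10))))
  raw$value[c(3, 17)] <- NA
  norm <- normalise_proteome(raw)
  grand <- median(norm$value, na.rm = TRUE)
  per_mouse <- tapply(norm$value, norm$mouse_id, median, na.rm = TRUE)
  expect_true(all(abs(per_mouse - grand) < 1e-9))
  # per-mouse shift: within-mouse rank order preserved
  m1_raw <- raw$value[raw$mouse_id == "m1"]
  m1_norm <- norm$value[norm$mouse_id == "m1"]
  expect_identical(order(m1_raw), order(m1_norm))
  # re-normalising the (unlogged) output is a no-op
  again <- normalise_proteome(dplyr::mutate(norm, value = 2^value))
  expect_equal(again$value, norm$value, tolerance = 1e-12)
})

test_that("normalisation reports offending non-positive cells", {
  raw <- make_long(matrix(c(1, -2, 3, 4), 2, 2,
                          dimnames = list(c("m1", "m2"), c("p1", "p2"))))
  expect_error(normalise_proteome(raw), "m2:p1")
})

test_that("protein CV matches forced arithmetic and a recomputation oracle", {
  m <- matrix(c(1, 3, 5, 5, 2, NA), 2, 3,
              dimnames = list(c("m1", "m2"), c("p1", "p2", "p3")))
  cv <- protein_cv(make_long(m), from_log2 = FALSE)
  expect_equal(cv$cv[cv$protein_id == "p1"], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cv$cv[cv$protein_id == "p2"], 0)
  expect_true(is.na(cv$cv[cv$protein_id == "p3"]))  # single observation

  set.seed(5)
  vals <- matrix(2^rnorm(80, 10, 1), 8, 10,
                 dimnames = list(paste0("m", 1:8), sprintf("p%02d", 1:10)))
  got <- protein_cv(make_long(vals), from_log2 = FALSE)
  for (j in colnames(vals)) {
    expect_equal(got$cv[got$protein_id == j], sd(vals[, j]) / mean(vals[, j]),
                 tolerance = 1e-12)
  }
  expect_false(is.unsorted(rev(got$cv)))
})

test_that("fraction enrichment reproduces constructed ratios", {
  info <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    gene_symbol = c("ga", "gb", "gc", "gd"),
    fraction = c("mito", "mito", "pmf", "pmf")
  )
  # linear values; gene set {ga, gc}
  long <- tibble::tibble(
    mouse_id = "m1",
    protein_id = c("a", "b", "c", "d"),
    value = c(10, 10, 10, 10)
  )
  expect_equal(fraction_enrichment(long, info, c("ga", "gc"), from_log2 = FALSE), 1)
  long$value[1] <- 30  # mito share of set: 30/40; pmf share: 10/20
  expect_equal(fraction_enrichment(long, info, c("ga", "gc"), from_log2 = FALSE),
               (30 / 40) / (10 / 20))
  expect_error(fraction_enrichment(long, info, "nope", from_log2 = FALSE),
               "absent")
})
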