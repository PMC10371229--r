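test_that("identical config and seed give identical output; new seed differs", {
  cfg <- small_cfg(seed = 50)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$proteome, s2$proteome)
  expect_identical(s1$gtt, s2$gtt)
  expect_identical(s1$signatures, s2$signatures)
  s3 <- simulate_study(small_cfg(seed = 51))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("a single founder makes all mice genetically identical", {
  cfg <- small_cfg(seed = 1, n_founders = 1, n_mice = 12)
  G <- simulate_genotypes(cfg)$dosage
  expect_true(all(apply(G, 2, function(x) length(unique(x)) == 1)))
})

test_that("marker maps are strictly increasing and configs validated", {
  cfg <- small_cfg(seed = 2)
  mk <- simulate_genotypes(cfg)$markers
  by_chr <- split(mk$pos_bp, mk$chromosome)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  expect_error(sim_config(markers_per_chromosome = 1), "at least 2")
  expect_error(sim_config(cis_h2 = 1), "fraction")
  expect_error(sim_config(cis_h2 = 0.9, latent_share = 0.3), "<= 1")
})

test_that("kinship recomputed from the emitted founder mosaics matches", {
  cfg <- small_cfg(seed = 3, n_mice = 30)
  geno <- simulate_genotypes(cfg)
  # rebuild dosages from the founder labels + allele states by brute force
  lab1 <- geno$founders$hap1
  lab2 <- geno$founders$hap2
  fa <- geno$founder_alleles
  reb <- matrix(0, nrow(lab1), ncol(lab1))
  for (i in seq_len(nrow(lab1))) {
    for (m in seq_len(ncol(lab1))) {
      reb[i, m] <- fa[lab1[i, m], m] + fa[lab2[i, m], m]
    }
  }
  dimnames(reb) <- dimnames(geno$dosage)
  expect_identical(reb, geno$dosage)
  expect_equal(kinship_matrix(geno$dosage), oracle_kinship(reb),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cis heritability is recovered by per-protein regression", {
  cfg <- sim_config(n_mice = 400, n_chromosomes = 3, markers_per_chromosome = 25,
                    n_proteins_per_fraction = 30, cis_h2 = 0.5,
                    latent_share = 0.1, proportion_cis = 0.8,
                    proportion_trans = 0, n_causal_proteins = 3,
                    missing_rate = 0, seed = 4)
  geno <- simulate_genotypes(cfg)
  prot <- simulate_proteome(cfg, geno)
  truth <- prot$truth$cis_qtl_map
  r2 <- vapply(seq_len(nrow(truth)), function(i) {
    y <- prot$truth$complete_values[, truth$protein_id[i]]
    x <- geno$dosage[, truth$marker_id[i]]
    summary(lm(y ~ x))$r.squared
  }, numeric(1))
  expect_equal(mean(r2), 0.5, tolerance = 0.05)
})

test_that("all variance sources off gives constant proteins", {
  cfg <- small_cfg(seed = 5, cis_h2 = 0, latent_share = 0,
                   n_latent_factors = 0, noise_sd = 0, missing_rate = 0,
                   n_confounded_proteins = 0)
  prot <- simulate_proteome(cfg, simulate_genotypes(cfg))
  spread <- tapply(prot$proteome$value, prot$proteome$protein_id, sd)
  expect_true(all(spread < 1e-12))
})

test_that("missingness is injected at the configured MCAR rate", {
  cfg <- small_cfg(seed = 6, n_mice = 100, n_proteins_per_fraction = 50,
                   missing_rate = 0.4)
  prot <- simulate_proteome(cfg, simulate_genotypes(cfg))
  present <- tapply(!is.na(prot$proteome$value), prot$proteome$protein_id, mean)
  # each protein present in about 60% of mice; binomial CI at n = 100
  expect_equal(mean(present), 0.6, tolerance = 0.02)
  expect_true(all(present > 0.6 - 4 * sqrt(0.24 / 100)))
})

test_that("the GTT round-trips the stored Matsuda targets", {
  cfg <- small_cfg(seed = 7)
  st <- simulate_study(cfg)
  got <- matsuda_index(st$gtt)
  tg <- st$truth$targets
  expect_equal(got$matsuda[match(tg$mouse_id, got$mouse_id)], tg$matsuda,
               tolerance = 1e-9)
})

test_that("the degenerate GTT model gives every mouse exp(b0)", {
  cfg <- small_cfg(seed = 8, causal_effect_sd = 0, adiposity_effect = 0,
                   trait_noise_sd = 0)
  st <- simulate_study(cfg)
  m <- matsuda_index(st$gtt)$matsuda
  expect_equal(m, rep(10, length(m)), tolerance = 1e-9)
})

test_that("body composition satisfies its mass constraints", {
  st <- simulate_study(small_cfg(seed = 9))
  bc <- st$bodycomp
  expect_true(all(bc$fat_mass >= 0 & bc$lean_mass >= 0))
  expect_true(all(bc$fat_mass + bc$lean_mass <= bc$body_mass))
})

test_that("signature database plants reversers and validates the universe", {
  cfg <- small_cfg(seed = 10)
  genes <- sprintf("g%03d", 1:60)
  fp <- genes[1:8]
  db <- simulate_signature_db(cfg, fp, genes)
  expect_error(simulate_signature_db(cfg, c(fp, "missing_gene"), genes),
               "missing_gene")
  # rankings are complete permutations of the universe
  one <- db$signatures[db$signatures$compound == "cpd_001" &
                         db$signatures$cell_line == "CL1", ]
  expect_setequal(one$gene, genes)
  expect_identical(one$rank, seq_along(genes))
  # planted reversers place fingerprint genes low; neutrals do not
  mean_rank <- db$signatures |>
    dplyr::filter(gene %in% fp) |>
    dplyr::group_by(compound) |>
    dplyr::summarise(mr = mean(rank), .groups = "drop")
  planted <- mean_rank$mr[mean_rank$compound %in% db$reversers$compound]
  neutral <- mean_rank$mr[!mean_rank$compound %in% db$reversers$compound]
  expect_gt(min(planted), max(length(genes) * 0.7, mean(neutral)))
})

test_that("screen truth is recovered by hit calling at the design rates", {
  cfg <- small_cfg(seed = 11)
  sc <- simulate_screen(cfg)
  calls <- purrr::map(sc$plates, call_hits)
  for (md in names(calls)) {
    truth_ids <- sc$actives$compound[sc$actives$mode == md]
    called <- calls[[md]]$compound[calls[[md]]$is_hit]
    # planted effect 0.75 of window vs threshold 0.5: high sensitivity expected
    expect_gte(mean(truth_ids %in% called), 0.75)
    expect_lte(length(setdiff(called, truth_ids)), 2)
  }
})
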