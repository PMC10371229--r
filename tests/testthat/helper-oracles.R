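# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

options(irfinger.quiet = TRUE)

# one-line Matsuda arithmetic
oracle_matsuda <- function(g0, i0, gmean, imean) {
  10000 / sqrt(g0 * i0 * gmean * imean)
}

# brute-force weighted-KS running score: walk the ranking gene by gene
oracle_wks <- function(genes, metric, set, w) {
  N <- length(genes)
  hits <- genes %in% set
  denom_hit <- sum(abs(metric[hits])^w)
  denom_miss <- N - sum(hits)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      cur <- cur + abs(metric[i])^w / denom_hit
    } else {
      cur <- cur - 1 / denom_miss
    }
    run[i] <- cur
  }
  top <- max(run)
  bottom <- min(run)
  if (top >= -bottom) top else bottom  # exact ties resolve positive
}

# O(n^2 m) kinship: explicit double loop over mice on standardised dosages
oracle_kinship <- function(G) {
  sds <- apply(G, 2, sd)
  A <- G[, sds > 0, drop = FALSE]
  A <- sweep(sweep(A, 2, colMeans(A)), 2, apply(A, 2, sd), "/")
  n <- nrow(A)
  m <- ncol(A)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- sum(A[i, ] * A[j, ]) / m
    }
  }
  K
}

# per-marker OLS LOD, computed naively with lm()
oracle_ols_lod <- function(y, G, covariates = NULL) {
  n <- length(y)
  X0 <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, covariates)
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  vapply(seq_len(ncol(G)), function(m) {
    rss1 <- sum(stats::lm.fit(cbind(X0, G[, m]), y)$residuals^2)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
}

# step-down Storey q-values, written as the literal min-over-larger-p loop
oracle_qvalues <- function(p, pi0) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- which(p >= p[i])
    q[i] <- min(vapply(candidates, function(j) {
      pi0 * m * p[j] / sum(p <= p[j])
    }, numeric(1)), 1)
  }
  q
}

small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_mice = 60, n_chromosomes = 3, markers_per_chromosome = 20,
    n_proteins_per_fraction = 25, n_causal_proteins = 3,
    n_compounds = 30, n_reversers = 3, n_screen_actives_per_mode = 4,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# a deterministic toy GTT record builder
toy_gtt <- function(mouse = "m1", glucose, insulin_0, insulin_15,
                    times = c(0, 15, 30, 45, 60, 90)) {
  tibble::tibble(
    mouse_id = mouse,
    time_min = times,
    glucose = glucose,
    insulin = c(insulin_0, insulin_15, rep(NA_real_, length(times) - 2))
  )
}
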