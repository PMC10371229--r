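#' Simulate glucose-tolerance curves and body composition
#'
#' Draws a target log Matsuda Index for every mouse from the causal model
#' `log(M) = b0 + sum_j beta_j * protein_j + gamma * adiposity + eps` (sums
#' over the planted causal proteins, on their standardised latent-free
#' biological signals: hidden/batch structure contaminates measurements, not
#' physiology)
#' and then constructs glucose/insulin curves that reproduce the target
#' exactly: glucose follows a fixed bolus-response shape with per-mouse
#' variation (measured at 0, 15, 30, 45, 60, 90 min), insulin is measured at
#' 0 and 15 min, and a single positive insulin multiplier is solved so that
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` equals the target. Body
#' composition is tied to the same adiposity latent that confounds a subset
#' of proteins.
#'
#' Units are arbitrary but internally consistent; the Matsuda Index is
#' scale-equivariant, not unit-free.
#'
#' @param cfg A [sim_config()].
#' @param proteome Output of [simulate_proteome()].
#' @param b0 Baseline log Matsuda (default `log(10)`).
#'
#' @return A list with `gtt` (long tibble: `mouse_id`, `time_min`, `glucose`,
#'   `insulin` with `NA` where insulin was not sampled), `bodycomp`
#'   (`mouse_id`, `fat_mass`, `lean_mass`, `body_mass`), and `targets`
#'   (`mouse_id`, `log_matsuda`, `matsuda`).
#' @export
simulate_gtt <- function(cfg, proteome, b0 = log(10)) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- proteome$truth
  set.seed(derive_seed(cfg$seed, "gtt"))

  # causal inputs are the latent-free biological protein signals: hidden
  # (batch-like) structure contaminates measurements, not physiology
  vals <- truth$signal_values %||% truth$complete_values
  n <- nrow(vals)
  mouse_ids <- rownames(vals)
  a <- truth$adiposity_latent[mouse_ids]

  causal <- truth$causal_proteins
  z <- scale(vals[, causal$protein_id, drop = FALSE])
  eps <- rnorm(n, 0, cfg$trait_noise_sd)
  log_m <- b0 + drop(z %*% causal$effect) + cfg$adiposity_effect * a + eps
  target <- exp(log_m)

  times <- c(0, 15, 30, 45, 60, 90)
  shape <- c(1, 1.9, 2.4, 2.1, 1.8, 1.4)
  g0 <- pmax(3, 8 + 0.8 * rnorm(n))
  amp <- pmax(0.5, 1 + 0.15 * rnorm(n))

  i0_base <- 1
  i15_base <- 2.5

  gtt <- purrr::map_dfr(seq_len(n), function(i) {
    g <- g0[i] * (1 + (shape - 1) * amp[i])
    gmean <- mean(g)
    imean_base <- mean(c(i0_base, i15_base))
    s <- 10000 / (target[i] * sqrt(g[1] * i0_base * gmean * imean_base))
    if (s <= 0) {
      # unreachable for positive targets; kept as a defensive guard
      warn(sprintf("non-positive insulin multiplier for %s; regenerating", mouse_ids[i]))
      s <- abs(s) + 1e-6
    }
    ins <- c(s * i0_base, s * i15_base, rep(NA_real_, length(times) - 2L))
    tibble::tibble(
      mouse_id = mouse_ids[i],
      time_min = times,
      glucose = g,
      insulin = ins
    )
  })

  adip_pct <- pmin(60, pmax(3, 15 + 5 * a))
  body <- pmax(18, 28 + 3 * rnorm(n) + 0.15 * (adip_pct - 15))
  fat <- adip_pct / 100 * body
  lean <- 0.75 * (body - fat)
  bodycomp <- tibble::tibble(
    mouse_id = mouse_ids,
    fat_mass = fat,
    lean_mass = lean,
    body_mass = body
  )

  list(
    gtt = gtt,
    bodycomp = bodycomp,
    targets = tibble::tibble(mouse_id = mouse_ids, log_matsuda = unname(log_m),
                             matsuda = unname(target))
  )
}
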