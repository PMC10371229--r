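#' Simulate a fractionated muscle proteome with genetic architecture
#'
#' Builds log2 protein abundances for two fractions (mitochondrial and
#' post-mitochondrial) on top of simulated genotypes. Each protein is placed
#' at a genomic position (its gene). A configurable proportion of proteins is
#' cis-driven (local marker within the 2 Mbp window of the gene), a smaller
#' proportion is trans-driven (marker on another chromosome), and the rest
#' carry no genetic effect. All proteins load on shared hidden factors
#' (batch-like structure) and Gaussian noise; components are standardised so
#' `cis_h2` is the expected local-marker R-squared. A subset of non-genetic
#' proteins is loaded on a latent adiposity confounder shared with the
#' glucose-tolerance simulator. Missingness is injected completely at random.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#'
#' @return A list with:
#' \describe{
#'   \item{proteome}{long tibble: `mouse_id`, `protein_id`, `value` (log2
#'     abundance, `NA` when missing).}
#'   \item{protein_info}{tibble: `protein_id`, `gene_symbol`, `fraction`,
#'     `chromosome`, `pos_bp`, `genetic_class`.}
#'   \item{truth}{`sim_truth` list: cis/trans driver map, causal proteins
#'     with signed effects, confounded protein ids, the latent adiposity
#'     vector, and the complete (pre-missingness) value matrix.}
#' }
#' @export
simulate_proteome <- function(cfg, genotypes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$cis_h2 >= 1) abort("cis_h2 must be < 1")
  set.seed(derive_seed(cfg$seed, "proteome"))

  n <- cfg$n_mice
  dosage <- genotypes$dosage
  markers <- genotypes$markers
  p_total <- 2L * cfg$n_proteins_per_fraction
  mouse_ids <- rownames(dosage)

  protein_ids <- sprintf("P%04d", seq_len(p_total))
  gene_symbols <- sprintf("g%04d", seq_len(p_total))
  fraction <- rep(c("mito", "pmf"), each = cfg$n_proteins_per_fraction)

  n_cis <- round(cfg$proportion_cis * p_total)
  n_trans <- round(cfg$proportion_trans * p_total)
  genetic_class <- rep("none", p_total)
  cls_idx <- sample.int(p_total)
  genetic_class[cls_idx[seq_len(n_cis)]] <- "cis"
  if (n_trans > 0) genetic_class[cls_idx[n_cis + seq_len(n_trans)]] <- "trans"

  # usable (polymorphic) markers only
  poly <- which(apply(dosage, 2, sd) > 0.1)
  if (length(poly) < 2L) abort("genotypes are essentially monomorphic")

  # causal proteins: cis-driven, negative effect on log Matsuda. Their driver
  # loci are planted mutually near-uncorrelated, and every other genetic
  # protein is kept off those loci: marginal association cannot separate
  # co-localised pQTL, so the planted truth is made identifiable by design
  cis_idx <- which(genetic_class == "cis")
  causal_idx <- sample(cis_idx, cfg$n_causal_proteins)
  C <- abs(stats::cor(dosage[, poly, drop = FALSE]))
  causal_drivers <- integer(0)
  for (mk in sample(seq_along(poly))) {
    if (length(causal_drivers) == cfg$n_causal_proteins) break
    if (all(C[mk, causal_drivers] <= 0.2)) causal_drivers <- c(causal_drivers, mk)
  }
  if (length(causal_drivers) < cfg$n_causal_proteins) {
    abort("could not place mutually uncorrelated causal loci; enlarge the genome")
  }
  near_causal <- apply(C[, causal_drivers, drop = FALSE], 1, max) > 0.5
  free_markers <- poly[!near_causal]

  chrom <- integer(p_total)
  pos <- numeric(p_total)
  driver <- rep(NA_character_, p_total)
  for (j in seq_len(p_total)) {
    if (genetic_class[j] == "cis") {
      mk <- if (j %in% causal_idx) {
        poly[causal_drivers[match(j, causal_idx)]]
      } else {
        sample(free_markers, 1L)
      }
      chrom[j] <- markers$chromosome[mk]
      pos[j] <- max(1, markers$pos_bp[mk] + round(runif(1, -1e6, 1e6)))
      driver[j] <- markers$marker_id[mk]
    } else if (genetic_class[j] == "trans") {
      mk <- sample(free_markers, 1L)
      other <- setdiff(seq_len(cfg$n_chromosomes), markers$chromosome[mk])
      chrom[j] <- if (length(other)) sample(other, 1L) else markers$chromosome[mk]
      pos[j] <- round(runif(1, 1, cfg$chromosome_length_bp))
      driver[j] <- markers$marker_id[mk]
    } else {
      chrom[j] <- sample.int(cfg$n_chromosomes, 1L)
      pos[j] <- round(runif(1, 1, cfg$chromosome_length_bp))
    }
  }

  std <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }

  k <- cfg$n_latent_factors
  fac <- if (k > 0) matrix(rnorm(n * k), n, k) else NULL
  noise_sd <- cfg$noise_sd %||% sqrt(max(0, 1 - cfg$cis_h2 - cfg$latent_share))

  adiposity_latent <- rnorm(n)
  names(adiposity_latent) <- mouse_ids
  none_idx <- which(genetic_class == "none")
  n_conf <- min(cfg$n_confounded_proteins, length(none_idx))
  confounded <- if (n_conf > 0) sample(none_idx, n_conf) else integer(0)

  # observed value = biological signal (genetic + residual + confounder)
  # plus a shared hidden-factor (batch-like) component; the trait simulator
  # consumes the biological signal only, so hidden structure is technical
  # nuisance for the scans to remove, never a causal path to the phenotype
  values <- matrix(0, n, p_total, dimnames = list(mouse_ids, protein_ids))
  latent_component <- matrix(0, n, p_total, dimnames = dimnames(values))
  mu <- rnorm(p_total, 20, 1.5)
  # causal signals are decorrelated in-sample: each causal protein's residual
  # is orthogonalised against the other causal genetic components and the
  # causal signals built before it, so marginal trait associations reflect
  # the planted effects rather than chance cross-correlations
  causal_genetics <- vapply(causal_idx,
                            function(j) std(dosage[, driver[j]]), numeric(n))
  causal_signals <- NULL
  for (j in seq_len(p_total)) {
    g_share <- if (genetic_class[j] == "none") 0 else cfg$cis_h2
    genetic <- if (g_share > 0) sqrt(g_share) * std(dosage[, driver[j]]) else 0
    latent <- if (k > 0 && cfg$latent_share > 0) {
      sqrt(cfg$latent_share) * std(drop(fac %*% rnorm(k)))
    } else 0
    res_sd <- if (is.null(cfg$noise_sd)) sqrt(max(0, 1 - g_share - cfg$latent_share)) else noise_sd
    eps_raw <- rnorm(n)
    if (j %in% causal_idx && res_sd > 0) {
      others <- cbind(causal_genetics[, causal_idx != j, drop = FALSE],
                      causal_signals)
      eps_raw <- lm.fit(cbind(1, others), eps_raw)$residuals
    }
    eps <- if (res_sd > 0) res_sd * std(eps_raw) else 0
    v <- genetic + eps
    if (j %in% causal_idx) causal_signals <- cbind(causal_signals, v)
    if (j %in% confounded) v <- v + cfg$confound_strength * adiposity_latent
    latent_component[, j] <- latent
    values[, j] <- mu[j] + v + latent
  }

  causal_effect <- -cfg$causal_effect_sd * runif(cfg$n_causal_proteins, 0.75, 1.25)

  complete_values <- values
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * p_total) < cfg$missing_rate, n, p_total)
    values[miss] <- NA_real_
  }

  protein_info <- tibble::tibble(
    protein_id = protein_ids,
    gene_symbol = gene_symbols,
    fraction = fraction,
    chromosome = chrom,
    pos_bp = pos,
    genetic_class = genetic_class
  )

  proteome <- tibble::as_tibble(as.data.frame.table(values, stringsAsFactors = FALSE))
  names(proteome) <- c("mouse_id", "protein_id", "value")

  truth <- structure(list(
    cis_qtl_map = tibble::tibble(
      protein_id = protein_ids[genetic_class != "none"],
      marker_id = driver[genetic_class != "none"],
      genetic_class = genetic_class[genetic_class != "none"],
      h2 = cfg$cis_h2
    ),
    causal_proteins = tibble::tibble(
      protein_id = protein_ids[causal_idx],
      gene_symbol = gene_symbols[causal_idx],
      effect = causal_effect
    ),
    confounded_proteins = protein_ids[confounded],
    adiposity_latent = adiposity_latent,
    complete_values = complete_values,
    signal_values = complete_values - latent_component
  ), class = "sim_truth")

  list(proteome = proteome, protein_info = protein_info, truth = truth)
}
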