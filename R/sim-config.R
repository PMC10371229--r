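#' Configuration for the synthetic study generator
#'
#' Defines the conditions of an in-silico Diversity Outbred style study:
#' a founder-mosaic population with kinship and local LD, a fractionated
#' muscle proteome with cis-acting genetic effects and hidden (batch-like)
#' factors, glucose-tolerance phenotypes driven causally by a subset of
#' proteins plus an adiposity confounder, a compound-signature database with
#' planted reversal compounds, and GLUT4-translocation screen plates with
#' planted actives.
#'
#' Protein values are built on a unit-variance scale from three variance
#' components: the local-marker (cis) share `cis_h2`, the hidden-factor share
#' `latent_share`, and a residual. When `noise_sd` is `NULL` the residual
#' standard deviation is chosen so the shares sum to one, making `cis_h2`
#' directly interpretable as the expected local-marker R-squared.
#'
#' @param n_mice Number of mice (default 215, the cohort scale the pipeline
#'   is designed around).
#' @param n_founders Number of founder strains in the mosaic (default 8).
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp Genome
#'   geometry for the marker map.
#' @param breakpoint_rate Expected number of founder-switch breakpoints per
#'   chromosome per haplotype.
#' @param n_proteins_per_fraction Proteins simulated in each of the two
#'   fractions (mitochondrial, post-mitochondrial).
#' @param cis_h2 Fraction of protein variance explained by the local marker
#'   for cis proteins, in \[0,1).
#' @param latent_share Fraction of protein variance carried by hidden factors.
#' @param n_latent_factors Number of hidden factors.
#' @param proportion_cis,proportion_trans Proportions of proteins given a
#'   local (cis) or distal (trans, other chromosome) genetic driver.
#' @param n_causal_proteins Number of cis proteins that causally (negatively)
#'   drive log Matsuda Index.
#' @param causal_effect_sd Typical magnitude of a causal protein effect on
#'   log Matsuda per SD of protein.
#' @param adiposity_effect Effect of the latent adiposity confounder on log
#'   Matsuda per SD (negative: fatter mice are less insulin sensitive).
#' @param n_confounded_proteins,confound_strength Number of non-causal
#'   proteins loaded on the adiposity latent, and loading strength.
#' @param trait_noise_sd SD of the residual on log Matsuda.
#' @param noise_sd Protein residual SD; `NULL` means the complement so that
#'   variance shares sum to 1.
#' @param missing_rate Missing-completely-at-random rate for protein values.
#' @param n_compounds,n_cell_lines Size of the compound-signature database.
#' @param n_reversers Planted signature reversers (compounds that push the
#'   fingerprint genes to the bottom of their rankings).
#' @param reversal_strength Strength of the planted reversal (shift, in SD of
#'   the ranking score, applied to fingerprint genes; large = near-bottom).
#' @param n_screen_actives_per_mode Planted actives per screen mode.
#' @param screen_effect Planted active response as a fraction of the assay
#'   window above the mode's reference control (must exceed 0.5 to exceed the
#'   hit threshold in expectation).
#' @param screen_noise_sd Gaussian well noise, percentage points of GLUT4 at
#'   the plasma membrane.
#' @param n_replicates,n_control_replicates Wells per compound / per control.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mice = 215L,
                       n_founders = 8L,
                       n_chromosomes = 5L,
                       markers_per_chromosome = 40L,
                       chromosome_length_bp = 1e8,
                       breakpoint_rate = 2,
                       n_proteins_per_fraction = 150L,
                       cis_h2 = 0.3,
                       latent_share = 0.2,
                       n_latent_factors = 5L,
                       proportion_cis = 0.25,
                       proportion_trans = 0.05,
                       n_causal_proteins = 6L,
                       causal_effect_sd = 0.8,
                       adiposity_effect = -0.35,
                       n_confounded_proteins = 5L,
                       confound_strength = 0.8,
                       trait_noise_sd = 0.5,
                       noise_sd = NULL,
                       missing_rate = 0.1,
                       n_compounds = 100L,
                       n_cell_lines = 3L,
                       n_reversers = 5L,
                       reversal_strength = 4,
                       n_screen_actives_per_mode = 8L,
                       screen_effect = 0.75,
                       screen_noise_sd = 2,
                       n_replicates = 4L,
                       n_control_replicates = 6L,
                       seed = 1L) {
  cfg <- list(
    n_mice = assert_count(n_mice, "n_mice"),
    n_founders = assert_count(n_founders, "n_founders"),
    n_chromosomes = assert_count(n_chromosomes, "n_chromosomes"),
    markers_per_chromosome = assert_count(markers_per_chromosome, "markers_per_chromosome"),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    breakpoint_rate = as.numeric(breakpoint_rate),
    n_proteins_per_fraction = assert_count(n_proteins_per_fraction, "n_proteins_per_fraction"),
    cis_h2 = assert_fraction(cis_h2, "cis_h2"),
    latent_share = assert_fraction(latent_share, "latent_share"),
    n_latent_factors = as.integer(n_latent_factors),
    proportion_cis = assert_fraction(proportion_cis, "proportion_cis", closed_right = TRUE),
    proportion_trans = assert_fraction(proportion_trans, "proportion_trans", closed_right = TRUE),
    n_causal_proteins = assert_count(n_causal_proteins, "n_causal_proteins"),
    causal_effect_sd = as.numeric(causal_effect_sd),
    adiposity_effect = as.numeric(adiposity_effect),
    n_confounded_proteins = as.integer(n_confounded_proteins),
    confound_strength = as.numeric(confound_strength),
    trait_noise_sd = as.numeric(trait_noise_sd),
    noise_sd = if (is.null(noise_sd)) NULL else as.numeric(noise_sd),
    missing_rate = assert_fraction(missing_rate, "missing_rate"),
    n_compounds = assert_count(n_compounds, "n_compounds"),
    n_cell_lines = assert_count(n_cell_lines, "n_cell_lines"),
    n_reversers = as.integer(n_reversers),
    reversal_strength = as.numeric(reversal_strength),
    n_screen_actives_per_mode = as.integer(n_screen_actives_per_mode),
    screen_effect = as.numeric(screen_effect),
    screen_noise_sd = as.numeric(screen_noise_sd),
    n_replicates = assert_count(n_replicates, "n_replicates"),
    n_control_replicates = assert_count(n_control_replicates, "n_control_replicates"),
    seed = as.integer(seed)
  )
  if (cfg$chromosome_length_bp <= 0) abort("`chromosome_length_bp` must be positive")
  if (cfg$n_latent_factors < 0) abort("`n_latent_factors` must be >= 0")
  if (cfg$markers_per_chromosome < 2L) {
    abort("`markers_per_chromosome` must be at least 2")
  }
  if (cfg$cis_h2 + cfg$latent_share > 1) {
    abort("cis_h2 + latent_share must be <= 1 (variance shares)")
  }
  if (cfg$proportion_cis + cfg$proportion_trans > 1) {
    abort("proportion_cis + proportion_trans must be <= 1")
  }
  if (!is.null(cfg$noise_sd) && cfg$noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (cfg$n_causal_proteins > floor(cfg$proportion_cis * 2 * cfg$n_proteins_per_fraction)) {
    abort("n_causal_proteins exceeds the number of cis proteins available")
  }
  structure(cfg, class = "sim_config")
}

#' Configuration for the protein QTL genome scan
#'
#' @param n_permutations Phenotype permutations used for genome-wide
#'   significance (default 1000).
#' @param alpha_cis Genome-wide significance level for cis calls
#'   (default 0.1).
#' @param alpha_trans Genome-wide significance level for trans calls
#'   (default 0.05).
#' @param cis_window_bp Half-width of the cis window around the protein's
#'   gene position, base pairs, inclusive (default 2 Mbp).
#' @param n_factors Hidden factors removed from the protein matrix before
#'   scanning (default 10).
#' @param use_kinship Model genetic relatedness as a random effect.
#' @param seed Seed for the permutations.
#'
#' @return A `scan_config` list.
#' @export
scan_config <- function(n_permutations = 1000L,
                        alpha_cis = 0.1,
                        alpha_trans = 0.05,
                        cis_window_bp = 2e6,
                        n_factors = 10L,
                        use_kinship = TRUE,
                        seed = 1L) {
  if (alpha_cis <= 0 || alpha_cis >= 1 || alpha_trans <= 0 || alpha_trans >= 1) {
    abort("alpha levels must lie strictly between 0 and 1")
  }
  if (cis_window_bp < 0) abort("`cis_window_bp` must be >= 0")
  structure(list(
    n_permutations = assert_count(n_permutations, "n_permutations"),
    alpha_cis = as.numeric(alpha_cis),
    alpha_trans = as.numeric(alpha_trans),
    cis_window_bp = as.numeric(cis_window_bp),
    n_factors = as.integer(n_factors),
    use_kinship = isTRUE(use_kinship),
    seed = as.integer(seed)
  ), class = "scan_config")
}
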