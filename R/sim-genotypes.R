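#' Simulate founder-mosaic genotypes for an outbred population
#'
#' Each mouse carries two haplotypes per chromosome, each a mosaic of founder
#' segments with Poisson-distributed breakpoints; marker dosages in \[0, 2\]
#' are the sum of the two founder allele states. Because segments are shared
#' across mice drawn from a small founder pool, the population has nontrivial
#' kinship and local linkage disequilibrium, which is what the mixed-model
#' scan and the cis-window classification need to be exercised against.
#'
#' @param cfg A [sim_config()].
#'
#' @return A list with:
#' \describe{
#'   \item{dosage}{numeric matrix, mice x markers, values in \[0, 2\].}
#'   \item{markers}{tibble with `marker_id`, `chromosome`, `pos_bp`
#'     (1-based physical positions, strictly increasing per chromosome).}
#'   \item{founders}{integer arrays (mice x markers x 2) of founder labels,
#'     kept so relatedness can be recomputed from the mosaics directly.}
#'   \item{founder_alleles}{founders x markers 0/1 allele matrix.}
#' }
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$markers_per_chromosome < 2L) abort("markers_per_chromosome < 2")
  set.seed(derive_seed(cfg$seed, "genotypes"))

  n <- cfg$n_mice
  n_chr <- cfg$n_chromosomes
  mpc <- cfg$markers_per_chromosome
  len <- cfg$chromosome_length_bp
  m <- n_chr * mpc

  # evenly spaced marker grid with deterministic jitter, strictly increasing
  markers <- purrr::map_dfr(seq_len(n_chr), function(chr) {
    base <- seq(from = len / (mpc + 1), by = len / (mpc + 1), length.out = mpc)
    jitter <- runif(mpc, -0.2, 0.2) * len / (mpc + 1)
    pos <- round(sort(base + jitter))
    pos <- pmax(1, pos)
    # enforce strict monotonicity after rounding
    for (i in seq_along(pos)[-1]) if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
    tibble::tibble(
      marker_id = sprintf("chr%02d_m%03d", chr, seq_len(mpc)),
      chromosome = chr,
      pos_bp = pos
    )
  })

  founder_alleles <- matrix(rbinom(cfg$n_founders * m, 1L, 0.5),
                            nrow = cfg$n_founders, ncol = m)
  rownames(founder_alleles) <- sprintf("F%02d", seq_len(cfg$n_founders))
  colnames(founder_alleles) <- markers$marker_id

  lab1 <- matrix(0L, n, m)
  lab2 <- matrix(0L, n, m)
  for (chr in seq_len(n_chr)) {
    idx <- which(markers$chromosome == chr)
    pos <- markers$pos_bp[idx]
    for (i in seq_len(n)) {
      for (h in 1:2) {
        nbk <- rpois(1L, cfg$breakpoint_rate)
        bks <- sort(runif(nbk, 0, len))
        seg <- findInterval(pos, bks) + 1L
        fids <- sample.int(cfg$n_founders, nbk + 1L, replace = TRUE)
        lab <- fids[seg]
        if (h == 1L) lab1[i, idx] <- lab else lab2[i, idx] <- lab
      }
    }
  }

  col_idx <- seq_len(m)
  dosage <- matrix(0, n, m)
  for (i in seq_len(n)) {
    dosage[i, ] <- founder_alleles[cbind(lab1[i, ], col_idx)] +
      founder_alleles[cbind(lab2[i, ], col_idx)]
  }
  rownames(dosage) <- sprintf("mouse_%03d", seq_len(n))
  colnames(dosage) <- markers$marker_id
  dimnames(lab1) <- dimnames(lab2) <- dimnames(dosage)

  list(
    dosage = dosage,
    markers = markers,
    founders = list(hap1 = lab1, hap2 = lab2),
    founder_alleles = founder_alleles
  )
}
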