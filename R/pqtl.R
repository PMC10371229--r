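#' Classify a pQTL peak as cis, trans, or neither
#'
#' Two-tier rule: a peak is **cis** if it lies on the protein's chromosome
#' within `cis_window_bp` of the gene position (inclusive at both ends) and
#' its genome-wide permutation p-value is below `alpha_cis` (default 0.1);
#' otherwise it is **trans** if its p-value is below the stricter
#' `alpha_trans` (default 0.05); otherwise **none**. A local peak with
#' `alpha_trans <= p < alpha_cis` is therefore still called cis, while the
#' same p outside the window is called nothing.
#'
#' @param peak_chromosome,peak_pos_bp Peak marker coordinates.
#' @param genome_wide_p Permutation p-value of the peak.
#' @param protein_chromosome,protein_pos_bp Protein gene coordinates.
#' @param cfg A [scan_config()].
#'
#' @return `"cis"`, `"trans"` or `"none"`.
#' @export
classify_pqtl <- function(peak_chromosome, peak_pos_bp, genome_wide_p,
                          protein_chromosome, protein_pos_bp,
                          cfg = scan_config()) {
  if (is.na(protein_chromosome) || is.na(protein_pos_bp)) {
    abort("protein has no genomic position; cannot classify cis/trans")
  }
  local <- peak_chromosome == protein_chromosome &&
    abs(peak_pos_bp - protein_pos_bp) <= cfg$cis_window_bp
  if (local && genome_wide_p < cfg$alpha_cis) return("cis")
  if (genome_wide_p < cfg$alpha_trans) return("trans")
  "none"
}

#' Map protein QTL for every protein
#'
#' The full mapping stage: proteins are z-scored and hidden factors removed
#' ([residualize_factors()]), a kinship matrix is computed once, then each
#' protein gets a mixed-model genome scan, a permutation genome-wide p-value
#' for its peak, and a cis/trans classification against its gene position.
#' The peak is the single global maximum-LOD marker, ties broken by lowest
#' (chromosome, position).
#'
#' @param proteome Long tibble: `mouse_id`, `protein_id`, `value`.
#' @param genotypes Dosage matrix, mice x markers (rownames = mouse ids).
#' @param markers Tibble: `marker_id`, `chromosome`, `pos_bp`.
#' @param protein_info Tibble: `protein_id`, `chromosome`, `pos_bp`.
#' @param cfg A [scan_config()].
#' @param covariates Optional numeric matrix of covariates aligned with the
#'   rows of `genotypes`.
#'
#' @return Tibble (one row per protein): `protein_id`, `peak_marker`,
#'   `chromosome`, `pos_bp`, `lod`, `genome_wide_p`, `classification`,
#'   `lambda`, `n_used`.
#' @export
map_pqtl <- function(proteome, genotypes, markers, protein_info,
                     cfg = scan_config(), covariates = NULL) {
  mice <- rownames(genotypes)
  wide <- proteome |>
    tidyr::pivot_wider(names_from = "protein_id", values_from = "value")
  if (!setequal(wide$mouse_id, mice)) {
    mismatch <- c(setdiff(wide$mouse_id, mice), setdiff(mice, wide$mouse_id))
    abort(sprintf("proteome and genotypes are misaligned; first mismatch: %s",
                  mismatch[1]))
  }
  pm <- as.matrix(wide[match(mice, wide$mouse_id), -1, drop = FALSE])
  rownames(pm) <- mice
  pm <- residualize_factors(pm, k = min(cfg$n_factors, nrow(pm) - 1L))
  K <- if (cfg$use_kinship) kinship_matrix(genotypes) else NULL

  marker_pos <- markers[match(colnames(genotypes), markers$marker_id), ]
  # tie-break order for equal LOD: lowest (chromosome, position)
  tie_order <- order(marker_pos$chromosome, marker_pos$pos_bp)

  info <- protein_info[match(colnames(pm), protein_info$protein_id), ]

  res <- purrr::map_dfr(seq_len(ncol(pm)), function(j) {
    pid <- colnames(pm)[j]
    prot_cfg <- cfg
    prot_cfg$seed <- (cfg$seed %% 100000L) * 7919L + j
    scan <- genome_scan(pm[, j], genotypes, K = K, covariates = covariates,
                        cfg = prot_cfg)
    lod_t <- scan$lod[tie_order]
    peak_idx <- tie_order[which.max(lod_t)]
    perm <- permutation_threshold(scan_replace_peak(scan, peak_idx), prot_cfg)
    cls <- classify_pqtl(
      marker_pos$chromosome[peak_idx], marker_pos$pos_bp[peak_idx],
      perm$genome_wide_p, info$chromosome[j], info$pos_bp[j], cfg
    )
    tibble::tibble(
      protein_id = pid,
      peak_marker = marker_pos$marker_id[peak_idx],
      chromosome = marker_pos$chromosome[peak_idx],
      pos_bp = marker_pos$pos_bp[peak_idx],
      lod = unname(scan$lod[peak_idx]),
      genome_wide_p = perm$genome_wide_p,
      classification = cls,
      lambda = scan$lambda,
      n_used = scan$n_used
    )
  })
  log_kv("map_pqtl",
         n_cis = sum(res$classification == "cis"),
         n_trans = sum(res$classification == "trans"))
  res
}

# swap the scan's peak for the tie-broken one so the permutation p refers to it
scan_replace_peak <- function(scan, peak_idx) {
  scan$peak_marker <- names(scan$lod)[peak_idx]
  scan$peak_lod <- unname(scan$lod[peak_idx])
  scan
}
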