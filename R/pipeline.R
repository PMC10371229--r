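#' Run the full fingerprint-to-compound pipeline on a synthetic study
#'
#' Orchestrates every stage end to end: simulate the study, compute per-mouse
#' phenotypes (Matsuda Index, adiposity), presence-filter the proteome,
#' associate proteins with log2 Matsuda (adiposity-adjusted, Storey
#' q-values), map pQTL with the kinship mixed model and permutation
#' thresholds, intersect negative associations with cis-pQTL into the
#' fingerprint, score compound signatures for connectivity against the
#' fingerprint, call screen hits in the three GLUT4 assay modes, and
#' integrate everything into the overall compound ranking.
#'
#' Every stage writes a plain TSV artifact (UTF-8, `NA` missing values, a
#' `#` comment header carrying the package version, seed and config hash)
#' into `out_dir`; existing artifacts are left untouched unless
#' `force = TRUE`, so reruns are idempotent and a run with the same config
#' and seed is byte-identical. The configuration is echoed to
#' `config.json` and the ground truth to `truth.json`.
#'
#' @param cfg A [sim_config()]; its `seed` drives every stage.
#' @param scan A [scan_config()] for the pQTL stage (its seed is re-derived
#'   from `cfg$seed`).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param q_threshold Association q-value threshold feeding the fingerprint.
#' @param force Overwrite existing artifacts.
#'
#' @return An `ir_pipeline` list: `study`, `phenotypes`, `associations`,
#'   `pqtl`, `fingerprint`, `connectivity`, `hits`, `scores`, `ranked`,
#'   `paths`.
#' @export
run_pipeline <- function(cfg = sim_config(), scan = scan_config(),
                         out_dir = NULL, q_threshold = 0.05, force = FALSE) {
  scan$seed <- cfg$seed
  study <- simulate_study(cfg)
  log_kv("stage", name = "simulate", seed = cfg$seed,
         version = as.character(packageVersion("irfinger")))

  phenotypes <- phenotype_table(study$gtt, study$bodycomp)
  proteome <- presence_filter(study$proteome, min_fraction = 0.5)
  log_kv("stage", name = "phenotype", n_mice = nrow(phenotypes),
         n_proteins = dplyr::n_distinct(proteome$protein_id))

  assoc <- run_association_scan(proteome, phenotypes,
                                trait = "matsuda", covariates = "adiposity",
                                log2_trait = TRUE,
                                protein_info = study$protein_info)
  log_kv("stage", name = "associate",
         n_significant = sum(assoc$q_value < q_threshold, na.rm = TRUE))

  adip <- phenotypes$adiposity[match(rownames(study$genotypes), phenotypes$mouse_id)]
  pqtl <- map_pqtl(proteome, study$genotypes, study$markers,
                   study$protein_info, cfg = scan,
                   covariates = matrix(adip, ncol = 1,
                                       dimnames = list(NULL, "adiposity")))
  log_kv("stage", name = "mapqtl", n_pqtl = sum(pqtl$classification != "none"))

  fingerprint <- build_fingerprint(assoc, pqtl, q_threshold = q_threshold)
  if (nrow(fingerprint) == 0L) {
    abort("pipeline stopped: the fingerprint is empty at this q threshold")
  }

  connectivity <- connectivity_score(study$signatures, fingerprint,
                                     weight_exponent = 0)
  log_kv("stage", name = "connect", n_compounds = nrow(connectivity))

  hits <- purrr::map(study$screen, call_hits)
  scores <- build_score_matrix(hits, connectivity)
  ranked <- rank_compounds(scores)
  log_kv("stage", name = "integrate", top_compound = ranked$compound[1])

  result <- structure(list(
    study = study, phenotypes = phenotypes, proteome = proteome,
    associations = assoc, pqtl = pqtl, fingerprint = fingerprint,
    connectivity = connectivity, hits = hits, scores = scores,
    ranked = ranked, config = cfg, scan_config = scan,
    q_threshold = q_threshold, paths = NULL
  ), class = "ir_pipeline")

  if (!is.null(out_dir)) {
    result$paths <- write_pipeline_artifacts(result, out_dir, force = force)
  }
  result
}

write_pipeline_artifacts <- function(pipe, out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- pipe$config
  seed <- cfg$seed
  study <- pipe$study
  paths <- character(0)

  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    if (!file.exists(path) || force) {
      write_artifact(df, path, seed, cfg)
    } else {
      log_kv("stage_skipped", file = file)
    }
    paths[[file]] <<- path
  }
  emit_matrix <- function(m, file, id_name) {
    path <- file.path(out_dir, file)
    if (!file.exists(path) || force) {
      write_matrix_tsv(m, path, id_name = id_name,
                       comment = artifact_header(seed, cfg))
    } else {
      log_kv("stage_skipped", file = file)
    }
    paths[[file]] <<- path
  }

  emit_matrix(t(study$genotypes), "genotypes.tsv", "marker_id")
  emit(study$markers, "markers.tsv")
  for (fr in c("mito", "pmf")) {
    ids <- study$protein_info$protein_id[study$protein_info$fraction == fr]
    wide <- study$proteome |>
      dplyr::filter(.data$protein_id %in% ids) |>
      tidyr::pivot_wider(names_from = "protein_id", values_from = "value")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$mouse_id
    emit_matrix(m, sprintf("proteome_%s.tsv", fr), "mouse_id")
  }
  emit(study$gtt, "gtt.tsv")
  emit(study$bodycomp, "bodycomp.tsv")
  emit(pipe$phenotypes, "phenotypes.tsv")
  emit(protein_cv(pipe$proteome), "protein_stats.tsv")
  for (fr in unique(pipe$associations$fraction)) {
    emit(dplyr::filter(pipe$associations, .data$fraction == fr),
         sprintf("associations_%s.tsv", fr))
  }
  emit(pipe$pqtl, "pqtl.tsv")
  emit(tibble::as_tibble(pipe$fingerprint), "fingerprint.tsv")

  gmt_path <- file.path(out_dir, "fingerprint.gmt")
  if (!file.exists(gmt_path) || force) export_query_set(pipe$fingerprint, gmt_path)
  paths[["fingerprint.gmt"]] <- gmt_path

  emit(study$signatures, "signatures.tsv")
  conn_wide <- pipe$connectivity |>
    dplyr::mutate(per_line = purrr::map(.data$per_line, ~ tibble::as_tibble(as.list(.x)))) |>
    tidyr::unnest("per_line")
  emit(conn_wide, "connectivity.tsv")
  for (md in names(study$screen)) {
    emit(study$screen[[md]], sprintf("screen_%s.tsv", md))
    emit(tibble::as_tibble(pipe$hits[[md]]), sprintf("hits_%s.tsv", md))
  }
  emit(tibble::as_tibble(pipe$scores), "score_matrix.tsv")
  emit(rank_compounds(pipe$scores, top_k = 20), "top20.tsv")

  truth_path <- file.path(out_dir, "truth.json")
  if (!file.exists(truth_path) || force) {
    truth <- study$truth
    jsonlite::write_json(list(
      causal_proteins = truth$causal_proteins,
      cis_qtl_map = truth$cis_qtl_map,
      confounded_proteins = truth$confounded_proteins,
      fingerprint_genes = truth$fingerprint_genes,
      reverser_compounds = truth$reverser_compounds,
      dual_active = truth$dual_active,
      screen_actives = truth$screen_actives
    ), truth_path, auto_unbox = TRUE, digits = NA)
  }
  paths[["truth.json"]] <- truth_path

  cfg_path <- file.path(out_dir, "config.json")
  if (!file.exists(cfg_path) || force) {
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  paths[["config.json"]] <- cfg_path
  paths
}

#' @export
print.ir_pipeline <- function(x, ...) {
  cat("<ir_pipeline>\n")
  cat(sprintf("  fingerprint: %d proteins; consensus compounds scored: %d\n",
              nrow(x$fingerprint), nrow(x$scores)))
  cat(sprintf("  top compound: %s (overall %.3f)\n",
              x$ranked$compound[1], x$ranked$overall[1]))
  invisible(x)
}
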