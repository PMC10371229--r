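#' Simulate a compound-signature database
#'
#' Emulates an L1000-style database: for every compound x cell line, a
#' complete ranking of the gene universe (rank 1 = most up-regulated by the
#' compound). Planted "reverser" compounds systematically push the query
#' (fingerprint) genes toward the bottom of their rankings — the expression
#' pattern of a compound that down-regulates the insulin-resistance
#' signature — with tunable strength; all other compounds rank genes
#' uniformly at random.
#'
#' @param cfg A [sim_config()].
#' @param fingerprint_genes Character vector of query genes to plant reversal
#'   against; must be a subset of `universe`.
#' @param universe Character vector of all genes covered by the signatures.
#'
#' @return A list with `signatures` (long tibble: `compound`, `cell_line`,
#'   `gene`, `rank`) and `reversers` (tibble: `compound`, `strength`).
#' @export
simulate_signature_db <- function(cfg, fingerprint_genes, universe) {
  stopifnot(inherits(cfg, "sim_config"))
  missing_genes <- setdiff(fingerprint_genes, universe)
  if (length(missing_genes)) {
    abort(paste0("fingerprint genes absent from the universe: ",
                 paste(missing_genes, collapse = ", ")))
  }
  if (!length(universe)) abort("empty gene universe")
  set.seed(derive_seed(cfg$seed, "signatures"))

  compounds <- sprintf("cpd_%03d", seq_len(cfg$n_compounds))
  cell_lines <- sprintf("CL%d", seq_len(cfg$n_cell_lines))
  n_rev <- max(0L, min(cfg$n_reversers, cfg$n_compounds))
  reversers <- compounds[seq_len(n_rev)]
  ng <- length(universe)
  in_set <- universe %in% fingerprint_genes

  signatures <- purrr::map_dfr(compounds, function(cpd) {
    strength <- if (cpd %in% reversers) cfg$reversal_strength else 0
    purrr::map_dfr(cell_lines, function(cl) {
      score <- rnorm(ng) - strength * in_set
      ord <- order(score, decreasing = TRUE)
      tibble::tibble(
        compound = cpd,
        cell_line = cl,
        gene = universe[ord],
        rank = seq_len(ng)
      )
    })
  })

  list(
    signatures = signatures,
    reversers = tibble::tibble(compound = reversers, strength = cfg$reversal_strength)
  )
}
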