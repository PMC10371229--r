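#' Simulate a complete in-silico study with known ground truth
#'
#' Runs every generator in order — genotypes, proteome, glucose-tolerance
#' phenotypes, compound-signature database, screen plates — wiring the ground
#' truth through: the planted causal (negative, cis-driven) proteins define
#' the true fingerprint genes, the signature database plants reversers
#' against exactly those genes, and the first planted reverser is also made
#' active in every screen mode (a "dual-active" that should top the final
#' integrated ranking).
#'
#' @param cfg A [sim_config()].
#'
#' @return An `ir_study` list: `genotypes`, `markers`, `proteome`,
#'   `protein_info`, `gtt`, `bodycomp`, `signatures`, `screen`, and `truth`
#'   (a `sim_truth` with `causal_proteins`, `cis_qtl_map`,
#'   `fingerprint_genes`, `reverser_compounds`, `dual_active`,
#'   `screen_actives`, `targets`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  geno <- simulate_genotypes(cfg)
  prot <- simulate_proteome(cfg, geno)
  gtt <- simulate_gtt(cfg, prot)

  truth <- prot$truth
  fingerprint_genes <- truth$causal_proteins$gene_symbol
  universe <- prot$protein_info$gene_symbol
  sigs <- simulate_signature_db(cfg, fingerprint_genes, universe)
  dual <- if (nrow(sigs$reversers)) sigs$reversers$compound[1] else NULL
  screen <- simulate_screen(cfg, dual_active = dual)

  truth$fingerprint_genes <- fingerprint_genes
  truth$reverser_compounds <- sigs$reversers
  truth$dual_active <- dual
  truth$screen_actives <- screen$actives
  truth$targets <- gtt$targets

  structure(list(
    config = cfg,
    genotypes = geno$dosage,
    markers = geno$markers,
    founders = geno$founders,
    founder_alleles = geno$founder_alleles,
    proteome = prot$proteome,
    protein_info = prot$protein_info,
    gtt = gtt$gtt,
    bodycomp = gtt$bodycomp,
    signatures = sigs$signatures,
    screen = screen$plates,
    truth = truth
  ), class = "ir_study")
}

#' @export
print.ir_study <- function(x, ...) {
  cat("<ir_study>\n")
  cat(sprintf("  %d mice, %d markers, %d proteins (%d causal, %d cis-driven)\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$protein_info),
              nrow(x$truth$causal_proteins),
              sum(x$protein_info$genetic_class == "cis")))
  cat(sprintf("  %d compounds x %d cell lines, %d planted reversers\n",
              x$config$n_compounds, x$config$n_cell_lines,
              nrow(x$truth$reverser_compounds)))
  invisible(x)
}
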