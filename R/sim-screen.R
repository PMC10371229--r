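#' Simulate GLUT4-translocation screen plates
#'
#' Emits well-level measurements (% of total GLUT4 at the plasma membrane)
#' for the three assay modes: basal agonist (compound alone), insulin
#' sensitiser (compound + 1 nM insulin) and insulin-resistance reverser
#' (compound + 100 nM insulin after palmitate). Each mode carries the control
#' wells its hit rule needs (basal; 1 nM insulin; 100 nM insulin; 100 nM
#' insulin + palmitate). Planted actives respond at `screen_effect` of the
#' assay window above the mode's reference control, neutral compounds sit at
#' the reference level, and all wells get Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @param compounds Character vector of compound ids (defaults to the ids
#'   used by [simulate_signature_db()]).
#' @param dual_active Optional compound id forced to be an active in every
#'   mode (used to plant a "signature reverser that also works in the dish").
#'
#' @return A list with `plates` (one tibble per mode: `mode`, `well_type`,
#'   `control_type`, `compound`, `replicate`, `value`) and `actives`
#'   (tibble: `compound`, `mode`, `effect`).
#' @export
simulate_screen <- function(cfg, compounds = sprintf("cpd_%03d", seq_len(cfg$n_compounds)),
                            dual_active = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "screen"))

  levels <- c(basal = 10, insulin_1nM = 18, insulin_100nM = 50, insulin_palmitate = 25)
  modes <- c("basal_agonist", "sensitiser", "reverser")
  reference <- c(basal_agonist = "basal", sensitiser = "insulin_1nM",
                 reverser = "insulin_palmitate")
  controls_needed <- list(
    basal_agonist = c("basal", "insulin_100nM"),
    sensitiser = c("basal", "insulin_1nM", "insulin_100nM"),
    reverser = c("basal", "insulin_100nM", "insulin_palmitate")
  )

  n_active <- max(0L, min(cfg$n_screen_actives_per_mode, length(compounds)))
  actives <- purrr::map_dfr(modes, function(md) {
    ids <- sample(setdiff(compounds, dual_active), n_active)
    if (!is.null(dual_active)) ids <- c(dual_active, ids[seq_len(max(0, n_active - 1L))])
    tibble::tibble(compound = ids, mode = md, effect = cfg$screen_effect)
  })

  plates <- purrr::map(modes, function(md) {
    ref <- levels[[reference[[md]]]]
    window <- levels[["insulin_100nM"]] - ref
    ctrl <- purrr::map_dfr(controls_needed[[md]], function(ct) {
      tibble::tibble(
        mode = md, well_type = "control", control_type = ct,
        compound = NA_character_,
        replicate = seq_len(cfg$n_control_replicates),
        value = pmax(0, levels[[ct]] + rnorm(cfg$n_control_replicates, 0, cfg$screen_noise_sd))
      )
    })
    active_ids <- actives$compound[actives$mode == md]
    cmp <- purrr::map_dfr(compounds, function(cpd) {
      mu <- if (cpd %in% active_ids) ref + cfg$screen_effect * window else ref
      tibble::tibble(
        mode = md, well_type = "compound", control_type = NA_character_,
        compound = cpd,
        replicate = seq_len(cfg$n_replicates),
        value = pmax(0, mu + rnorm(cfg$n_replicates, 0, cfg$screen_noise_sd))
      )
    })
    dplyr::bind_rows(ctrl, cmp)
  })
  names(plates) <- modes

  list(plates = plates, actives = actives)
}
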