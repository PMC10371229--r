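#' Call hits on a GLUT4-translocation screen plate
#'
#' Applies the 50%-of-control rule for the plate's mode, on replicate-mean
#' responses, with a strict `>` at the boundary:
#' \describe{
#'   \item{basal_agonist}{threshold = basal + 0.5 x (insulin100 - basal),
#'     i.e. 50% of the insulin response above basal. The literal alternative
#'     "50% of the 100 nM insulin level" is available via
#'     `basal_rule = "absolute"`.}
#'   \item{sensitiser}{threshold = insulin1 + 0.5 x (insulin100 - insulin1).}
#'   \item{reverser}{threshold = palmitate control + 0.5 x (insulin100 -
#'     palmitate control).}
#' }
#' Control values are replicate means. If the 100 nM insulin control does not
#' exceed the mode's reference control there is no assay window and the call
#' is refused.
#'
#' @param plate Tibble: `mode`, `well_type` (`"control"`/`"compound"`),
#'   `control_type`, `compound`, `replicate`, `value` (% GLUT4 at the plasma
#'   membrane).
#' @param basal_rule `"response"` (default) or `"absolute"`, see above.
#'
#' @return An `ir_hits` tibble: `compound`, `mode`, `response` (replicate
#'   mean), `threshold`, `is_hit`.
#' @export
call_hits <- function(plate, basal_rule = c("response", "absolute")) {
  basal_rule <- match.arg(basal_rule)
  mode <- unique(plate$mode)
  if (length(mode) != 1L) abort("`plate` must contain exactly one mode")
  reference <- switch(mode,
    basal_agonist = "basal",
    sensitiser = "insulin_1nM",
    reverser = "insulin_palmitate",
    abort(sprintf("unknown mode `%s`", mode))
  )
  ctrl <- plate |>
    dplyr::filter(.data$well_type == "control") |>
    dplyr::group_by(.data$control_type) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ctrl_val <- function(type) {
    v <- ctrl$value[ctrl$control_type == type]
    if (!length(v)) abort(sprintf("mode `%s` requires a `%s` control", mode, type))
    v
  }
  ins100 <- ctrl_val("insulin_100nM")
  ref <- ctrl_val(reference)
  if (ins100 <= ref) {
    abort(sprintf(
      "no assay window in mode `%s`: insulin_100nM (%.2f) <= %s (%.2f)",
      mode, ins100, reference, ref))
  }
  threshold <- if (mode == "basal_agonist" && basal_rule == "absolute") {
    0.5 * ins100
  } else {
    ref + 0.5 * (ins100 - ref)
  }
  out <- plate |>
    dplyr::filter(.data$well_type == "compound") |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(response = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(mode = mode, threshold = threshold,
                  is_hit = .data$response > threshold) |>
    dplyr::select("compound", "mode", "response", "threshold", "is_hit")
  log_kv("call_hits", mode = mode, n_hits = sum(out$is_hit))
  structure(out, class = c("ir_hits", class(out)))
}

#' Overlap counts between the three assays' hit sets
#'
#' @param hits_list List of three `ir_hits` tibbles over the same compound
#'   universe (one per mode).
#'
#' @return Tibble of region counts for the three-set Venn decomposition
#'   (exclusive regions plus each pairwise and the triple intersection).
#' @export
overlap_summary <- function(hits_list) {
  sets <- purrr::map(hits_list, ~ .x$compound[.x$is_hit])
  names(sets) <- purrr::map_chr(hits_list, ~ unique(.x$mode))
  modes <- names(sets)
  if (length(modes) != 3L) abort("expected hit calls for exactly three modes")
  a <- sets[[1]]; b <- sets[[2]]; c <- sets[[3]]
  tibble::tibble(
    region = c(modes[1], modes[2], modes[3],
               paste(modes[1], modes[2], sep = "&"),
               paste(modes[1], modes[3], sep = "&"),
               paste(modes[2], modes[3], sep = "&"),
               paste(modes, collapse = "&")),
    count = c(
      length(setdiff(setdiff(a, b), c)),
      length(setdiff(setdiff(b, a), c)),
      length(setdiff(setdiff(c, a), b)),
      length(setdiff(intersect(a, b), c)),
      length(setdiff(intersect(a, c), b)),
      length(setdiff(intersect(b, c), a)),
      length(intersect(intersect(a, b), c))
    )
  )
}

#' z-score a vector of compound scores
#'
#' `(x - mean) / SD` with the sample (n-1) standard deviation; missing
#' entries are excluded from mean/SD and propagate as `NA`.
#'
#' @param values Numeric vector.
#'
#' @return z-scores (mean 0, sample SD 1 over the non-missing entries).
#' @export
zscore_column <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) abort("need at least 2 non-missing values to z-score")
  s <- sd(values[ok])
  if (s == 0) abort("zero standard deviation; z-scores undefined")
  (values - mean(values[ok])) / s
}

#' Overall compound score
#'
#' The integration formula: the mean of the three GLUT4-assay z-scores plus
#' the z-scored connectivity term,
#' `(z_bas + z_sens + z_rev) / 3 + z_cmap_reversal`.
#'
#' @param z_bas,z_sens,z_rev,z_cmap_reversal Numeric vectors (aligned).
#'
#' @return Numeric vector of overall scores.
#' @export
overall_score <- function(z_bas, z_sens, z_rev, z_cmap_reversal) {
  (z_bas + z_sens + z_rev) / 3 + z_cmap_reversal
}

#' Build the integrated compound score matrix
#'
#' Restricts to the consensus compounds found in both the screen and the
#' signature database, z-scores each assay's replicate-mean response and the
#' connectivity score over exactly that consensus set (z-scores are always
#' relative to the scored set), and combines them with [overall_score()].
#'
#' Sign convention: raw connectivity scores are negated before z-scoring
#' (`cmap_sign = "reversal-positive"`, the default) so that stronger reversal
#' of the fingerprint contributes positively to the overall score; set
#' `cmap_sign = "raw"` for the literal sum. A compound missing an assay gets
#' that z set to 0 (population-neutral) and is flagged.
#'
#' @param hits_list List of three `ir_hits` tibbles (modes `basal_agonist`,
#'   `sensitiser`, `reverser`).
#' @param connectivity Tibble from [connectivity_score()] (`compound`,
#'   `raw_score`).
#' @param cmap_sign `"reversal-positive"` (default) or `"raw"`.
#'
#' @return An `ir_scores` tibble: `compound`, `z_bas`, `z_sens`, `z_rev`,
#'   `z_cmap`, `overall`, `n_missing_assays`.
#' @export
build_score_matrix <- function(hits_list, connectivity,
                               cmap_sign = c("reversal-positive", "raw")) {
  cmap_sign <- match.arg(cmap_sign)
  responses <- purrr::map_dfr(hits_list, ~ dplyr::select(tibble::as_tibble(.x),
                                                         "compound", "mode", "response"))
  screen_compounds <- unique(responses$compound)
  consensus <- intersect(screen_compounds, connectivity$compound)
  if (!length(consensus)) abort("no consensus compounds between screen and signatures")
  log_kv("consensus_compounds", n = length(consensus))

  wide <- responses |>
    dplyr::filter(.data$compound %in% consensus) |>
    tidyr::pivot_wider(names_from = "mode", values_from = "response") |>
    dplyr::left_join(dplyr::select(connectivity, "compound", "raw_score"),
                     by = "compound")
  raw <- if (cmap_sign == "reversal-positive") -wide$raw_score else wide$raw_score

  z_or_zero <- function(x) {
    z <- zscore_column(x)
    dplyr::coalesce(z, 0)
  }
  out <- tibble::tibble(
    compound = wide$compound,
    z_bas = z_or_zero(wide$basal_agonist),
    z_sens = z_or_zero(wide$sensitiser),
    z_rev = z_or_zero(wide$reverser),
    z_cmap = z_or_zero(raw),
    n_missing_assays = rowSums(is.na(cbind(wide$basal_agonist, wide$sensitiser,
                                           wide$reverser)))
  ) |>
    dplyr::mutate(overall = overall_score(.data$z_bas, .data$z_sens,
                                          .data$z_rev, .data$z_cmap))
  structure(out, class = c("ir_scores", class(out)), cmap_sign = cmap_sign)
}

#' Rank compounds by overall score
#'
#' Descending by `overall`; ties broken by the connectivity z-score, then by
#' compound id, so the ranking is deterministic.
#'
#' @param scores An `ir_scores` tibble from [build_score_matrix()].
#' @param top_k Optionally keep only the first `top_k` rows.
#'
#' @return The ranked tibble with a `rank` column.
#' @export
rank_compounds <- function(scores, top_k = NULL) {
  if (nrow(scores) == 0L) abort("empty score matrix; nothing to rank")
  out <- scores |>
    dplyr::arrange(dplyr::desc(.data$overall), dplyr::desc(.data$z_cmap),
                   .data$compound) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  if (!is.null(top_k)) out <- dplyr::slice_head(out, n = top_k)
  out
}
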