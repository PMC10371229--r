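#' Matsuda Index of whole-body insulin sensitivity
#'
#' Computes, per mouse, `10000 / sqrt(G0 * I0 * Gmean * Imean)` from a
#' glucose-tolerance test: fasting glucose and insulin (time 0) times the
#' mean glucose and mean insulin over the test. Means include the baseline
#' (time 0) value by default, the convention of the original surrogate
#' derivation; set `include_baseline = FALSE` to average post-bolus
#' timepoints only. Higher values mean greater insulin sensitivity. The index
#' is scale-equivariant, not unit-free (doubling every glucose value halves
#' it), so glucose and insulin units only need to be consistent across mice.
#'
#' @param gtt Long tibble with columns `mouse_id`, `time_min`, `glucose`,
#'   `insulin` (`NA` at times where insulin was not sampled; time 0 must be
#'   present for both analytes).
#' @param include_baseline Include the time-0 value in the GTT means
#'   (default `TRUE`).
#'
#' @return Tibble with `mouse_id` and `matsuda`.
#' @export
matsuda_index <- function(gtt, include_baseline = TRUE) {
  required <- c("mouse_id", "time_min", "glucose", "insulin")
  if (!all(required %in% names(gtt))) {
    abort(paste0("`gtt` must have columns: ", paste(required, collapse = ", ")))
  }
  gtt |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      matsuda = .matsuda_one(.data$time_min, .data$glucose, .data$insulin,
                             include_baseline),
      .groups = "drop"
    )
}

.matsuda_one <- function(time_min, glucose, insulin, include_baseline = TRUE) {
  if (!any(time_min == 0)) abort("GTT record lacks a time-0 measurement")
  if (any(duplicated(time_min))) abort("GTT times must be strictly increasing")
  g <- glucose
  i <- insulin[!is.na(insulin)]
  ti <- time_min[!is.na(insulin)]
  if (any(g <= 0, na.rm = TRUE) || any(i <= 0)) {
    abort("all glucose and insulin concentrations must be positive")
  }
  if (!any(ti == 0)) abort("GTT record lacks a time-0 insulin measurement")
  g0 <- g[time_min == 0]
  i0 <- i[ti == 0]
  gm <- if (include_baseline) mean(g) else mean(g[time_min > 0])
  im <- if (include_baseline) mean(i) else mean(i[ti > 0])
  unname(10000 / sqrt(g0 * i0 * gm * im))
}

#' Adiposity as percent of body mass
#'
#' @param bodycomp Tibble with `mouse_id`, `fat_mass`, `body_mass` (grams).
#'
#' @return Tibble with `mouse_id` and `adiposity` (= 100 * fat / body mass).
#' @export
adiposity_percent <- function(bodycomp) {
  if (!all(c("mouse_id", "fat_mass", "body_mass") %in% names(bodycomp))) {
    abort("`bodycomp` must have columns mouse_id, fat_mass, body_mass")
  }
  if (any(bodycomp$body_mass <= 0)) abort("body_mass must be positive")
  if (any(bodycomp$fat_mass < 0)) abort("fat_mass must be non-negative")
  dplyr::transmute(bodycomp,
    mouse_id = .data$mouse_id,
    adiposity = 100 * .data$fat_mass / .data$body_mass
  ) |> tibble::as_tibble()
}

#' Per-mouse phenotype table
#'
#' Convenience wrapper combining [matsuda_index()] and [adiposity_percent()].
#'
#' @param gtt,bodycomp See [matsuda_index()] and [adiposity_percent()].
#' @param include_baseline Passed to [matsuda_index()].
#'
#' @return Tibble with `mouse_id`, `matsuda`, `adiposity`.
#' @export
phenotype_table <- function(gtt, bodycomp, include_baseline = TRUE) {
  dplyr::inner_join(
    matsuda_index(gtt, include_baseline),
    adiposity_percent(bodycomp),
    by = "mouse_id"
  )
}
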