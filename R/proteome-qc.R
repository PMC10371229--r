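#' Filter proteins on the fraction of mice they were observed in
#'
#' Retains proteins quantified (non-missing) in at least `min_fraction` of
#' mice; the boundary is inclusive, so with the default a protein seen in
#' exactly half of the mice is kept. Protein order is preserved and dropped
#' ids are logged.
#'
#' @param proteome Long tibble: `mouse_id`, `protein_id`, `value` (missing
#'   values as `NA`).
#' @param min_fraction Minimum observed fraction, default 0.5.
#'
#' @return The filtered long tibble.
#' @export
presence_filter <- function(proteome, min_fraction = 0.5) {
  if (nrow(proteome) == 0L) {
    warn("empty proteome; nothing to filter")
    return(proteome)
  }
  n_mice <- dplyr::n_distinct(proteome$mouse_id)
  presence <- proteome |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(presence = sum(!is.na(.data$value)) / n_mice, .groups = "drop")
  keep <- presence$protein_id[presence$presence >= min_fraction]
  dropped <- setdiff(presence$protein_id, keep)
  if (length(dropped)) {
    log_kv("presence_filter", n_dropped = length(dropped),
           dropped = paste(dropped, collapse = ";"))
  }
  dplyr::filter(proteome, .data$protein_id %in% keep)
}

#' Log2-transform and median-normalise a proteome
#'
#' Takes raw (linear-scale, positive) intensities, log2-transforms them and
#' centres every mouse to the grand median so between-mouse loading
#' differences are removed: after normalisation every mouse's median log2
#' intensity equals the global median. Missing values are left untouched and
#' ignored by the medians. Within-mouse protein rank order is preserved
#' (the correction is a per-mouse shift).
#'
#' @param proteome Long tibble: `mouse_id`, `protein_id`, `value` (raw
#'   positive intensity, `NA` allowed).
#'
#' @return Long tibble with `value` on the normalised log2 scale.
#' @export
normalise_proteome <- function(proteome) {
  bad <- which(!is.na(proteome$value) & proteome$value <= 0)
  if (length(bad)) {
    cells <- paste0(proteome$mouse_id[bad], ":", proteome$protein_id[bad])
    abort(paste0("non-positive intensities at ",
                 paste(head(cells, 10), collapse = ", "),
                 if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else ""))
  }
  out <- dplyr::mutate(proteome, value = log2(.data$value))
  grand <- median(out$value, na.rm = TRUE)
  out |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(value = .data$value - median(.data$value, na.rm = TRUE) + grand) |>
    dplyr::ungroup()
}

#' Per-protein coefficient of variation
#'
#' CV = sample SD / mean on the linear (unlogged) intensity scale — CVs of
#' log values are not scale-free — with missing values excluded. Proteins
#' with fewer than two observations or non-positive linear mean are flagged
#' (`cv = NA`) and excluded from the ranking. The result is ordered by
#' decreasing CV so it can feed enrichment analysis of proteins ranked by
#' variability directly.
#'
#' @param proteome Long tibble: `mouse_id`, `protein_id`, `value`.
#' @param from_log2 Are values log2 intensities (default `TRUE`)? If so they
#'   are unlogged before computing the CV.
#'
#' @return Tibble: `protein_id`, `n_obs`, `mean`, `sd`, `cv`, sorted by
#'   decreasing `cv` (flagged proteins last).
#' @export
protein_cv <- function(proteome, from_log2 = TRUE) {
  stats <- proteome |>
    dplyr::mutate(lin = if (from_log2) 2^.data$value else .data$value) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$lin)),
      mean = mean(.data$lin, na.rm = TRUE),
      sd = sd(.data$lin, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv = dplyr::if_else(.data$n_obs >= 2 & .data$mean > 0,
                          .data$sd / .data$mean, NA_real_)
    )
  flagged <- sum(is.na(stats$cv))
  if (flagged) log_kv("protein_cv", n_flagged = flagged)
  dplyr::arrange(stats, dplyr::desc(.data$cv))
}

#' Relative enrichment of a gene set in one fraction over the other
#'
#' Computes the share of total (linear-scale) abundance carried by a gene set
#' within the mitochondrial fraction, divided by the same share within the
#' post-mitochondrial fraction. A value of 2 means the set claims twice the
#' abundance share in the mitochondrial fraction.
#'
#' @param proteome Long tibble: `mouse_id`, `protein_id`, `value`.
#' @param protein_info Tibble with `protein_id`, `gene_symbol`, `fraction`
#'   (values `"mito"` and `"pmf"`).
#' @param geneset Character vector of gene symbols.
#' @param from_log2 Unlog values before summing (default `TRUE`).
#'
#' @return A single numeric ratio (mito share / pmf share).
#' @export
fraction_enrichment <- function(proteome, protein_info, geneset, from_log2 = TRUE) {
  df <- proteome |>
    dplyr::inner_join(protein_info, by = "protein_id") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(lin = if (from_log2) 2^.data$value else .data$value)
  in_set <- df$gene_symbol %in% geneset
  if (!any(in_set)) abort("gene set absent from both fractions")
  share <- df |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      share = sum(.data$lin[.data$gene_symbol %in% geneset]) / sum(.data$lin),
      .groups = "drop"
    )
  mito <- share$share[share$fraction == "mito"]
  pmf <- share$share[share$fraction == "pmf"]
  if (!length(mito) || !length(pmf)) abort("both fractions must be present")
  mito / pmf
}
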