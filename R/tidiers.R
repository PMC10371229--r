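#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the running enrichment curve
#'
#' @param x An `ir_enrichment` from [running_enrichment_score()].
#' @param ... Unused.
#'
#' @return Tibble: `gene`, `position`, `score`, `in_set`.
#' @method tidy ir_enrichment
#' @export
tidy.ir_enrichment <- function(x, ...) {
  x$running
}

#' One-row summary of an enrichment result
#'
#' @param x An `ir_enrichment`.
#' @param ... Unused.
#'
#' @return Tibble: `es`, `n_set`, `n_ranked`, `weight_exponent`.
#' @method glance ir_enrichment
#' @export
glance.ir_enrichment <- function(x, ...) {
  tibble::tibble(es = x$es, n_set = x$n_set, n_ranked = nrow(x$running),
                 weight_exponent = x$weight_exponent)
}

#' Tidy a genome scan into a per-marker table
#'
#' @param x An `ir_scan` from [genome_scan()].
#' @param ... Unused.
#'
#' @return Tibble: `marker_id`, `lod`.
#' @method tidy ir_scan
#' @export
tidy.ir_scan <- function(x, ...) {
  tibble::tibble(marker_id = names(x$lod), lod = unname(x$lod))
}

#' One-row summary of a genome scan
#'
#' @param x An `ir_scan`.
#' @param ... Unused.
#'
#' @return Tibble: `peak_marker`, `peak_lod`, `lambda` (kinship variance
#'   ratio), `n_used`.
#' @method glance ir_scan
#' @export
glance.ir_scan <- function(x, ...) {
  tibble::tibble(peak_marker = x$peak_marker, peak_lod = x$peak_lod,
                 lambda = x$lambda, n_used = x$n_used)
}

#' Tidy a fingerprint
#'
#' @param x An `ir_fingerprint`.
#' @param ... Unused.
#'
#' @return The fingerprint as a plain tibble.
#' @method tidy ir_fingerprint
#' @export
tidy.ir_fingerprint <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a fingerprint
#'
#' @param x An `ir_fingerprint`.
#' @param ... Unused.
#'
#' @return Tibble: `n_proteins`, `n_genes`, per-fraction counts and the
#'   strongest (most negative) effect.
#' @method glance ir_fingerprint
#' @export
glance.ir_fingerprint <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_genes = dplyr::n_distinct(x$gene_symbol),
    n_mito = if ("fraction" %in% names(x)) sum(x$fraction == "mito") else NA_integer_,
    n_pmf = if ("fraction" %in% names(x)) sum(x$fraction == "pmf") else NA_integer_,
    min_effect = if (nrow(x)) min(x$effect) else NA_real_
  )
}
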