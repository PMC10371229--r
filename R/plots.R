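#' Volcano plot of protein-trait associations
#'
#' Effect size against -log10 q-value, coloured by direction for proteins
#' below the significance threshold.
#'
#' @param assoc Results from [run_association_scan()].
#' @param q_threshold Highlight threshold (default 0.05).
#'
#' @return A ggplot.
#' @export
plot_volcano <- function(assoc, q_threshold = 0.05) {
  df <- assoc |>
    dplyr::filter(!.data$flagged) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$q_value < q_threshold & .data$effect < 0 ~ "negative",
        .data$q_value < q_threshold ~ "positive",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$effect, -log10(.data$q_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = "dotted",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(negative = "#2166ac", ns = "grey70",
                                            positive = "#b2182b")) +
    ggplot2::labs(x = "effect on log2 Matsuda Index per SD protein",
                  y = expression(-log[10] ~ "q"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of pQTL peaks
#'
#' @param pqtl Table from [map_pqtl()].
#'
#' @return A ggplot of peak LOD by genomic position, shaped by cis/trans
#'   class.
#' @export
plot_pqtl <- function(pqtl) {
  ggplot2::ggplot(pqtl, ggplot2::aes(.data$pos_bp / 1e6, .data$lod,
                                     colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "peak position (Mbp)", y = "LOD", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a running enrichment curve
#'
#' @param object An `ir_enrichment` from [running_enrichment_score()].
#' @param ... Unused.
#'
#' @return A ggplot of the running score with set-member positions marked.
#' @method autoplot ir_enrichment
#' @export
autoplot.ir_enrichment <- function(object, ...) {
  df <- object$running
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$score)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_rug(data = df[df$in_set, ], sides = "b", alpha = 0.6) +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", object$es)) +
    ggplot2::theme_minimal()
}

#' Heat-map of the top-ranked compounds' score matrix
#'
#' @param scores An `ir_scores` tibble from [build_score_matrix()].
#' @param top_k Number of compounds to show (default 20).
#'
#' @return A ggplot tile map of z-scores with compounds ordered by overall
#'   score.
#' @export
plot_score_matrix <- function(scores, top_k = 20) {
  ranked <- rank_compounds(scores, top_k = top_k)
  long <- ranked |>
    dplyr::select("compound", "z_bas", "z_sens", "z_rev", "z_cmap", "overall") |>
    tidyr::pivot_longer(-"compound", names_to = "score", values_to = "z") |>
    dplyr::mutate(compound = factor(.data$compound, levels = rev(ranked$compound)))
  ggplot2::ggplot(long, ggplot2::aes(.data$score, .data$compound, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
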