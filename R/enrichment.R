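#' Weighted Kolmogorov-Smirnov running enrichment score
#'
#' The single enrichment core shared by all three callers in the package:
#' GSEA on proteins ranked by trait effect size, GSEA on proteins ranked by
#' CV, and connectivity scoring of compound signatures against the
#' fingerprint. Walking down the ranking, a gene in the set increments the
#' running sum by `|metric|^weight_exponent` normalised by the total over set
#' members; a gene outside the set decrements it by `1 / (N - n_set)`. The
#' enrichment score is the signed extremum of the running sum, in \[-1, 1\]:
#' positive when the set concentrates at the top of the ranking, negative at
#' the bottom. With `weight_exponent = 0` the statistic is rank-only
#' (classic KS), appropriate for an unordered query set.
#'
#' Ties in the metric are broken by gene id so results are deterministic.
#'
#' @param ranking Tibble with columns `gene` and optionally `metric`
#'   (ranking statistic, sorted or not), or a character vector of genes
#'   already in rank order (metric-free; requires `weight_exponent = 0`).
#' @param gene_set Character vector; must intersect the ranking and must not
#'   equal the whole universe.
#' @param weight_exponent Weight on the metric (default 1; use 0 for
#'   rank-only).
#'
#' @return An `ir_enrichment` list: `es`, `running` (tibble: `gene`,
#'   `position`, `score`, `in_set`), `n_set`, `weight_exponent`.
#' @export
running_enrichment_score <- function(ranking, gene_set, weight_exponent = 1) {
  if (is.character(ranking)) {
    ranking <- tibble::tibble(gene = ranking, metric = NA_real_)
    if (weight_exponent != 0) {
      abort("a metric-free ranking requires weight_exponent = 0")
    }
  }
  if (anyDuplicated(ranking$gene)) abort("genes in the ranking must be unique")
  if (!"metric" %in% names(ranking) || all(is.na(ranking$metric))) {
    ord <- seq_len(nrow(ranking))
    metric <- rep(1, nrow(ranking))
  } else {
    ord <- order(-ranking$metric, ranking$gene)
    metric <- ranking$metric[ord]
  }
  genes <- ranking$gene[ord]
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) abort("gene set is disjoint from the ranking")
  if (nh == N) abort("gene set equals the whole universe; miss penalty undefined")

  w <- abs(metric)^weight_exponent
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  top <- max(running)
  bottom <- min(running)
  # signed extremum; an exact |top| == |bottom| tie resolves positive, the
  # convention of standard GSEA implementations
  es <- if (top >= -bottom) top else bottom

  structure(list(
    es = es,
    running = tibble::tibble(gene = genes, position = seq_len(N),
                             score = running, in_set = hit),
    n_set = nh,
    weight_exponent = weight_exponent
  ), class = "ir_enrichment")
}

#' @export
print.ir_enrichment <- function(x, ...) {
  cat(sprintf("<ir_enrichment> ES = %.4f (%d set genes in %d ranked, w = %g)\n",
              x$es, x$n_set, nrow(x$running), x$weight_exponent))
  invisible(x)
}

#' Permutation p-value for an enrichment score
#'
#' Null distribution by permuting set membership over the universe (random
#' sets of the same size); two-sided p with the +1 correction. Correct FDR
#' across many sets with [qvalues()] in `pi0 = 1` mode.
#'
#' @param ranking,gene_set,weight_exponent As in
#'   [running_enrichment_score()].
#' @param n_perm Number of permutations (at least 100).
#' @param seed Seed for the membership permutations.
#'
#' @return List: `es`, `p_value`, `perm_es`.
#' @export
es_permutation_p <- function(ranking, gene_set, weight_exponent = 1,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  obs <- running_enrichment_score(ranking, gene_set, weight_exponent)
  universe <- if (is.character(ranking)) ranking else ranking$gene
  set.seed(derive_seed(seed, "enrichment"))
  perm_es <- vapply(seq_len(n_perm), function(i) {
    running_enrichment_score(ranking, sample(universe, obs$n_set),
                             weight_exponent)$es
  }, numeric(1))
  p <- (1 + sum(abs(perm_es) >= abs(obs$es))) / (n_perm + 1)
  list(es = obs$es, p_value = p, perm_es = perm_es)
}

#' Connectivity scores of compound signatures against a query set
#'
#' Scores every compound x cell line signature for enrichment of the query
#' gene set (rank-only weighted KS by default, since the query is an
#' unordered set), then averages the enrichment score across cell lines into
#' the compound's raw connectivity score. Negative scores mean the compound
#' down-regulates the query — the reversal signal the pipeline looks for —
#' so the output is sorted ascending, strongest reversers first. Signatures
#' covering less than 90% of the query are scored on the intersection with a
#' logged coverage warning.
#'
#' @param signatures Long tibble: `compound`, `cell_line`, `gene`, `rank`
#'   (1 = most up-regulated).
#' @param query Character vector of query genes, or an `ir_fingerprint`
#'   (its `gene_symbol` column is used).
#' @param weight_exponent Weight on the (rank-derived) metric; default 0.
#'
#' @return Tibble: `compound`, `raw_score`, `n_cell_lines`, `coverage`,
#'   plus a list-column `per_line` of per-cell-line scores.
#' @export
connectivity_score <- function(signatures, query, weight_exponent = 0) {
  if (inherits(query, "ir_fingerprint")) query <- query$gene_symbol
  query <- unique(query)
  res <- signatures |>
    dplyr::group_by(.data$compound, .data$cell_line) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::summarise(
      # for w > 0 a rank-derived metric in (0, 1] stands in for the
      # (unavailable) expression statistic
      es = {
        g <- .data$gene
        rk <- .data$rank
        running_enrichment_score(
          tibble::tibble(gene = g, metric = 1 - (rk - 1) / length(rk)),
          intersect(query, g),
          weight_exponent = weight_exponent
        )$es
      },
      coverage = length(intersect(query, .data$gene)) / length(query),
      .groups = "drop"
    )
  low <- res |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(coverage = min(.data$coverage), .groups = "drop") |>
    dplyr::filter(.data$coverage < 0.9)
  if (nrow(low)) {
    log_kv("connectivity_low_coverage",
           compounds = paste(low$compound, collapse = ";"))
  }
  res |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      raw_score = mean(.data$es),
      n_cell_lines = dplyr::n(),
      coverage = min(.data$coverage),
      per_line = list(setNames(.data$es, .data$cell_line)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$raw_score)
}

#' Gene-set enrichment over a ranked protein list
#'
#' Convenience caller wrapping the shared weighted-KS core for the two GSEA
#' uses: proteins ranked by trait effect size and proteins ranked by CV.
#' Each set gets its running enrichment score and a gene-permutation p-value;
#' FDR across sets uses [qvalues()] with `pi0 = 1` (plain BH), appropriate
#' for the small numbers of sets typically tested.
#'
#' @param ranking Tibble with `gene` and `metric` (e.g. effect sizes from
#'   [run_association_scan()] joined to gene symbols, or CVs from
#'   [protein_cv()]).
#' @param gene_sets Named list of character vectors, or the tibble returned
#'   by [read_gmt()].
#' @param weight_exponent Metric weight (default 1).
#' @param n_perm Permutations per set (default 1000).
#' @param seed Seed for the permutation null.
#'
#' @return Tibble: `set`, `es`, `n_set`, `p_value`, `q_value`, ordered by
#'   `p_value`.
#' @export
enrichment_table <- function(ranking, gene_sets, weight_exponent = 1,
                             n_perm = 1000, seed = 1L) {
  if (is.data.frame(gene_sets)) {
    gene_sets <- setNames(gene_sets$genes, gene_sets$name)
  }
  res <- purrr::imap_dfr(gene_sets, function(genes, nm) {
    perm <- es_permutation_p(ranking, genes, weight_exponent = weight_exponent,
                             n_perm = n_perm, seed = seed)
    tibble::tibble(set = nm, es = perm$es,
                   n_set = length(intersect(genes, ranking$gene)),
                   p_value = perm$p_value)
  })
  res$q_value <- qvalues(res$p_value, pi0 = 1)
  dplyr::arrange(res, .data$p_value)
}
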