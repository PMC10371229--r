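#' Build the molecular fingerprint of insulin resistance
#'
#' Intersects the proteins negatively associated with insulin sensitivity
#' (effect < 0 and q below threshold in the association scan) with the
#' proteins carrying a cis-pQTL. The rationale: a negative association marks
#' a candidate driver of resistance ("up in IR"), and a cis genetic effect on
#' the protein's abundance argues that the protein differences are not a
#' consequence of the phenotype — so the association is plausibly causal.
#' Gene-symbol collisions (the same gene quantified in both fractions)
#' collapse to the entry with the smaller q-value. Entries are ordered by
#' effect size ascending (strongest negative first).
#'
#' @param assoc Association results from [run_association_scan()] (must
#'   contain `gene_symbol`; pass `protein_info` to the scan).
#' @param pqtl pQTL table from [map_pqtl()].
#' @param q_threshold Significance threshold on the association q-value
#'   (default 0.05; the threshold is a tunable, never baked in).
#'
#' @return An `ir_fingerprint` tibble: `protein_id`, `gene_symbol`,
#'   `fraction`, `effect`, `q_value`, `classification`, with attribute
#'   `direction = "up-in-IR"`. Empty (with a warning) if the intersection is
#'   empty.
#' @export
build_fingerprint <- function(assoc, pqtl, q_threshold = 0.05) {
  if (!"gene_symbol" %in% names(assoc)) {
    abort("`assoc` needs a gene_symbol column (run the scan with protein_info)")
  }
  fp <- assoc |>
    dplyr::filter(!.data$flagged, .data$effect < 0,
                  !is.na(.data$q_value), .data$q_value < q_threshold) |>
    dplyr::inner_join(
      dplyr::select(pqtl, "protein_id", "classification"),
      by = "protein_id"
    ) |>
    dplyr::filter(.data$classification == "cis") |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::slice_min(.data$q_value, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$effect) |>
    dplyr::select(dplyr::any_of(c("protein_id", "gene_symbol", "fraction",
                                  "effect", "q_value", "classification")))
  if (nrow(fp) == 0L) warn("fingerprint is empty: no negative cis-pQTL proteins")
  if ("fraction" %in% names(fp)) {
    counts <- table(fp$fraction)
    log_kv("fingerprint", total = nrow(fp),
           per_fraction = paste(names(counts), counts, sep = ":", collapse = ","))
  }
  structure(tibble::as_tibble(fp), class = c("ir_fingerprint", class(fp)),
            direction = "up-in-IR")
}

#' Annotate a fingerprint with human orthologues
#'
#' Joins human gene symbols from a two-column mapping (mouse symbol, human
#' symbol). Unmapped entries are retained and flagged, never dropped.
#'
#' @param fp An `ir_fingerprint`.
#' @param mapping Data frame whose first two columns are mouse and human
#'   symbols, or a path to a two-column TSV.
#'
#' @return The fingerprint with `human_symbol` and `mapped` columns.
#' @export
map_orthologues <- function(fp, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    lines <- readLines(mapping)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      abort(sprintf("malformed mapping row at line %d (expected 2 tab-separated fields)",
                    bad[1]))
    }
    mapping <- tibble::tibble(
      mouse_symbol = vapply(parts, `[[`, "", 1),
      human_symbol = vapply(parts, `[[`, "", 2)
    )
  }
  mapping <- tibble::as_tibble(mapping)
  names(mapping)[1:2] <- c("mouse_symbol", "human_symbol")
  out <- fp |>
    dplyr::left_join(mapping[, 1:2], by = c(gene_symbol = "mouse_symbol")) |>
    dplyr::mutate(mapped = !is.na(.data$human_symbol))
  structure(out, class = class(fp), direction = attr(fp, "direction"))
}

#' Export the fingerprint as a GMT query gene set
#'
#' Writes a single GMT line (set name, description, tab-separated gene
#' symbols) ready to be used as a connectivity query. The set is
#' single-directional ("up in IR"): reversal shows up as negative enrichment
#' of this one set, rather than the paired up/down query some connectivity
#' services use.
#'
#' @param fp An `ir_fingerprint` (non-empty).
#' @param path Output file.
#' @param name,description GMT fields.
#'
#' @return `path`, invisibly.
#' @export
export_query_set <- function(fp, path, name = "IR_fingerprint_up",
                             description = "proteins up in insulin resistance") {
  if (nrow(fp) == 0L) abort("cannot export an empty fingerprint")
  genes <- unique(fp$gene_symbol)
  if (any(grepl("[[:space:]]", genes))) {
    abort("gene symbols must not contain whitespace (GMT is tab-delimited)")
  }
  write_gmt(tibble::tibble(name = name, description = description,
                           genes = list(genes)), path)
  invisible(path)
}
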