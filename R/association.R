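#' Fit one protein-trait linear model
#'
#' Ordinary least squares of the (optionally log2-transformed) trait on a
#' single protein's abundance plus covariates:
#' `trait = alpha + beta * protein + covariates + eps`, on complete cases
#' only. The reported p-value is the two-sided Wald t-test on the protein
#' coefficient with `n - k - 1` degrees of freedom. A rank-deficient design
#' (e.g. a constant protein) yields a flagged result with `NA` effect and
#' p-value so it can be excluded from multiple-testing adjustment.
#'
#' Sign convention: a negative effect means more protein, lower insulin
#' sensitivity — the direction the fingerprint selects for.
#'
#' @param protein Numeric vector of protein values (NA = missing).
#' @param trait Numeric trait vector, aligned with `protein`.
#' @param covariates Optional numeric matrix / data frame of covariates,
#'   aligned rows.
#'
#' @return One-row tibble: `effect`, `se`, `t`, `p_value`, `n_used`,
#'   `flagged`.
#' @export
fit_protein_trait_model <- function(protein, trait, covariates = NULL) {
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cc <- !is.na(protein) & !is.na(trait)
  if (!is.null(covm)) cc <- cc & stats::complete.cases(covm)
  n <- sum(cc)
  k_cov <- if (is.null(covm)) 0L else ncol(covm)
  flagged_row <- tibble::tibble(effect = NA_real_, se = NA_real_, t = NA_real_,
                                p_value = NA_real_, n_used = n, flagged = TRUE)
  if (n < k_cov + 3L) return(flagged_row)
  X <- cbind(intercept = 1, protein = protein[cc],
             if (!is.null(covm)) covm[cc, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(flagged_row)
  y <- trait[cc]
  fit <- lm.fit(X, y)
  df <- n - ncol(X)
  if (df < 1L) return(flagged_row)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- fit$coefficients[["protein"]]
  tstat <- beta / se
  tibble::tibble(
    effect = beta, se = se, t = tstat,
    p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
    n_used = n, flagged = FALSE
  )
}

#' Protein-trait association scan
#'
#' Fits [fit_protein_trait_model()] for every protein against the trait
#' (log2 Matsuda Index by default) and adjusts p-values with Storey
#' [qvalues()], within each fraction separately unless `pool_fractions` is
#' set (fraction-specific significance is reported per fraction; pooling is
#' available but not the default). Results are ordered by `protein_id` for
#' determinism. Flagged fits (rank-deficient) are excluded from the q-value
#' input and carry `NA` q-values.
#'
#' @param proteome Long tibble: `mouse_id`, `protein_id`, `value`.
#' @param phenotypes Tibble with `mouse_id`, the trait column and any
#'   covariate columns; must contain exactly the mice of `proteome`.
#' @param trait Name of the trait column (default `"matsuda"`).
#' @param covariates Character vector of covariate column names (default
#'   `"adiposity"`; use `NULL` for the unadjusted model).
#' @param log2_trait Log2-transform the trait before fitting (default
#'   `TRUE`).
#' @param protein_info Optional tibble with `protein_id` and `fraction`
#'   (and `gene_symbol`, carried through) for per-fraction adjustment.
#' @param pool_fractions Compute q-values across all fractions jointly.
#'
#' @return Tibble: `protein_id`, (`gene_symbol`, `fraction` if available),
#'   `effect`, `se`, `p_value`, `q_value`, `n_used`, `flagged`.
#' @export
run_association_scan <- function(proteome, phenotypes, trait = "matsuda",
                                 covariates = "adiposity", log2_trait = TRUE,
                                 protein_info = NULL, pool_fractions = FALSE) {
  if (!trait %in% names(phenotypes)) {
    abort(sprintf("trait column `%s` not found in phenotypes", trait))
  }
  missing_cov <- setdiff(covariates, names(phenotypes))
  if (length(missing_cov)) {
    abort(paste0("covariate columns not found: ", paste(missing_cov, collapse = ", ")))
  }
  prot_mice <- sort(unique(proteome$mouse_id))
  pheno_mice <- sort(unique(phenotypes$mouse_id))
  mismatch <- c(setdiff(prot_mice, pheno_mice), setdiff(pheno_mice, prot_mice))
  if (length(mismatch)) {
    abort(sprintf("proteome and phenotypes are misaligned; first mismatch: %s",
                  mismatch[1]))
  }
  pheno <- phenotypes[match(prot_mice, phenotypes$mouse_id), ]
  y <- pheno[[trait]]
  if (log2_trait) {
    if (any(y <= 0, na.rm = TRUE)) abort("trait must be positive for log2 transform")
    y <- log2(y)
  }
  covm <- if (length(covariates)) as.matrix(pheno[, covariates, drop = FALSE]) else NULL

  wide <- proteome |>
    tidyr::pivot_wider(names_from = "protein_id", values_from = "value") |>
    dplyr::arrange(.data$mouse_id)
  stopifnot(identical(wide$mouse_id, prot_mice))
  pids <- setdiff(names(wide), "mouse_id")

  res <- purrr::map_dfr(pids, function(pid) {
    dplyr::mutate(fit_protein_trait_model(wide[[pid]], y, covm),
                  protein_id = pid, .before = 1)
  })

  if (!is.null(protein_info)) {
    keep <- intersect(c("protein_id", "gene_symbol", "fraction"), names(protein_info))
    res <- dplyr::left_join(res, protein_info[, keep], by = "protein_id")
  }
  grouping <- if (!pool_fractions && "fraction" %in% names(res)) "fraction" else character(0)
  res <- res |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(q_value = qvalues(ifelse(.data$flagged, NA, .data$p_value))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$protein_id)
  dplyr::relocate(res, "q_value", .after = "p_value")
}

#' Overlap of association results with and without a covariate
#'
#' Classifies proteins significant at `q_threshold` in both models, only in
#' the covariate-adjusted model, or only in the unadjusted model, keeping the
#' effect signs. Proteins significant only without the covariate are the
#' classic signature of confounding (e.g. adiposity-driven associations).
#'
#' @param results_with_cov,results_without_cov Scan results from
#'   [run_association_scan()] over the same protein universe.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#'
#' @return Tibble: `protein_id`, `effect_with`, `effect_without`, `category`
#'   in `consensus` / `only_with` / `only_without` / `neither`.
#' @export
consensus_overlap <- function(results_with_cov, results_without_cov,
                              q_threshold = 0.05) {
  if (!setequal(results_with_cov$protein_id, results_without_cov$protein_id)) {
    abort("the two result sets cover different protein universes")
  }
  dplyr::inner_join(
    dplyr::select(results_with_cov, "protein_id",
                  effect_with = "effect", q_with = "q_value"),
    dplyr::select(results_without_cov, "protein_id",
                  effect_without = "effect", q_without = "q_value"),
    by = "protein_id"
  ) |>
    dplyr::mutate(
      sig_with = !is.na(.data$q_with) & .data$q_with < q_threshold,
      sig_without = !is.na(.data$q_without) & .data$q_without < q_threshold,
      category = dplyr::case_when(
        .data$sig_with & .data$sig_without ~ "consensus",
        .data$sig_with ~ "only_with",
        .data$sig_without ~ "only_without",
        TRUE ~ "neither"
      )
    ) |>
    dplyr::select("protein_id", "effect_with", "effect_without",
                  "q_with", "q_without", "category")
}
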