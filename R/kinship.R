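#' Genomic kinship matrix
#'
#' Realised genetic relatedness `K = A A' / m` from column-standardised
#' marker dosages (monomorphic markers are dropped). K is symmetric and
#' positive semi-definite by construction and is used as the random-effect
#' covariance of the mixed-model genome scan.
#'
#' @param G Numeric matrix, mice x markers, dosages in \[0, 2\].
#'
#' @return Symmetric PSD matrix, mice x mice, with the mouse ids of `G`.
#' @export
kinship_matrix <- function(G) {
  if (ncol(G) < 2L) abort("need at least 2 markers")
  sds <- apply(G, 2, sd)
  keep <- which(sds > 0)
  if (!length(keep)) abort("all markers are monomorphic; kinship undefined")
  A <- scale(G[, keep, drop = FALSE])
  K <- tcrossprod(A) / length(keep)
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Remove hidden factors from a protein matrix
#'
#' A light-weight analogue of PEER-style latent-factor correction: each
#' protein is z-scored, the top `k` factors are extracted by truncated
#' singular value decomposition (missing cells mean-imputed for the
#' decomposition only), and every protein is replaced by its residual after
#' regression on those factors. Missing cells stay missing. With `k = 0` the
#' function is the identity on the z-scored input. The factor model is
#' deliberately pluggable: any matrix of per-mouse factors can be passed via
#' `factors` instead.
#'
#' @param pm Numeric matrix, mice x proteins, `NA` = missing.
#' @param k Number of factors to remove (default 10).
#' @param factors Optional pre-computed mice x k factor matrix.
#'
#' @return Matrix of residualised z-scores, same shape and dimnames, `NA`
#'   pattern preserved.
#' @export
residualize_factors <- function(pm, k = 10, factors = NULL) {
  n <- nrow(pm)
  if (is.null(factors) && k >= n) abort("k must be smaller than the number of mice")
  Z <- scale(pm)
  Z[, apply(pm, 2, function(x) sum(!is.na(x)) < 2 || sd(x, na.rm = TRUE) == 0)] <- 0
  if (is.null(factors)) {
    if (k == 0) return(Z)
    Z0 <- Z
    Z0[is.na(Z0)] <- 0
    sv <- svd(Z0, nu = k, nv = 0)
    factors <- sv$u[, seq_len(k), drop = FALSE]
  }
  Fm <- cbind(1, as.matrix(factors))
  out <- Z
  for (j in seq_len(ncol(Z))) {
    obs <- which(!is.na(Z[, j]))
    if (length(obs) > ncol(Fm)) {
      fit <- lm.fit(Fm[obs, , drop = FALSE], Z[obs, j])
      out[obs, j] <- fit$residuals
    }
  }
  out
}
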