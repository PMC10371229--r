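#' Storey q-values
#'
#' False-discovery-rate adjusted significance with an estimate of the null
#' proportion pi0. pi0 is estimated by the smoother method: the natural
#' estimates `mean(p > lambda) / (1 - lambda)` over a lambda grid are fitted
#' with a cubic smoothing spline and evaluated at the largest lambda, then
#' clipped to (0, 1\]. The q-value of p_i is
#' `pi0 * min over {j: p_j >= p_i} of m * p_j / rank_j`, i.e. pi0 times the
#' Benjamini-Hochberg step-up adjustment; forcing `pi0 = 1` therefore
#' reproduces BH exactly.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed; propagated).
#' @param pi0 Optional null-proportion override (e.g. `1` for plain BH).
#' @param lambda Grid for pi0 estimation.
#'
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) && (any(pv < 0) || any(pv > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  if (!length(pv)) return(out)
  if (is.null(pi0)) pi0 <- estimate_pi0(pv, lambda)
  q <- pmin(1, pi0 * p.adjust(pv, method = "BH"))
  out[ok] <- q
  out
}

#' Estimate the proportion of true nulls (pi0)
#'
#' @param p P-values (no `NA`).
#' @param lambda Grid of tuning values in (0, 1).
#'
#' @return pi0 in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m == 0) abort("no p-values")
  lambda <- sort(lambda)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (length(lambda) < 4 || m < 50) {
    pi0 <- min(1, pi0_l[length(pi0_l)])
  } else {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
  }
  min(max(pi0, 1 / m), 1)
}
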