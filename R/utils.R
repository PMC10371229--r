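#' @importFrom rlang abort warn inform %||% hash .data
#' @importFrom stats complete.cases setNames
#' @importFrom stats median sd var quantile rnorm runif rbinom rpois
#' @importFrom stats lm.fit optimize pt p.adjust smooth.spline predict
#' @importFrom utils packageVersion head
NULL

# machine-parseable log line: key=value pairs to stderr (suppressable via
# options(irfinger.quiet = TRUE))
log_kv <- function(event, ...) {
  if (isTRUE(getOption("irfinger.quiet", FALSE))) {
    return(invisible(NULL))
  }
  kv <- list(...)
  msg <- paste0(
    "event=", event,
    if (length(kv)) paste0(" ", paste0(names(kv), "=", unlist(kv), collapse = " ")) else ""
  )
  inform(msg)
  invisible(NULL)
}

# stable per-stage seed derived from a global seed; kept well below 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(
    genotypes = 11L, proteome = 23L, gtt = 37L, signatures = 53L,
    screen = 71L, permutations = 89L, enrichment = 101L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1009L + off
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a positive integer count, got %s", name, deparse(x)))
  }
  as.integer(x)
}

assert_fraction <- function(x, name, closed_right = FALSE) {
  hi_ok <- if (closed_right) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a fraction in [0,1%s, got %s",
                  name, if (closed_right) "]" else ")", deparse(x)))
  }
  as.numeric(x)
}
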