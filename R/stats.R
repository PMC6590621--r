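#' Unpaired Student's t-test
#'
#' Pooled-variance two-sample t-test, two-sided, as classically defined:
#' `t = (mean(x) - mean(y)) / (s_p * sqrt(1/n_a + 1/n_b))` with
#' `df = n_a + n_b - 2`.  Degenerate inputs (zero variance in both groups)
#' are resolved explicitly rather than erroring: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param welch If `TRUE` use the Welch (unequal-variance) form instead of
#'   the pooled form.
#' @return A one-row tibble with columns `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `degenerate`.
#' @examples
#' t_test_unpaired(c(1, 2, 3), c(2, 3, 4))
#' @export
t_test_unpaired <- function(x, y, welch = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("t_test_unpaired() needs at least 2 observations per group")
  }
  if (anyNA(x) || anyNA(y)) stop("t_test_unpaired() does not accept NA values")
  out <- tibble::tibble(
    t = NA_real_, df = NA_real_, p = NA_real_,
    mean_a = mean(x), mean_b = mean(y),
    n_a = length(x), n_b = length(y), degenerate = FALSE
  )
  if (var(x) == 0 && var(y) == 0) {
    out$df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) {
      out$t <- 0
      out$p <- 1
    } else {
      out$t <- sign(mean(x) - mean(y)) * Inf
      out$p <- 0
      out$degenerate <- TRUE
    }
    return(out)
  }
  fit <- stats::t.test(x, y, var.equal = !welch)
  out$t <- unname(fit$statistic)
  out$df <- unname(fit$parameter)
  out$p <- fit$p.value
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, mapped back to input order and
#' clipped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust(): p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
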