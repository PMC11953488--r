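#' Spearman rank correlation with a two-sided p-value
#'
#' The correlation is the Pearson correlation of mid-ranks (ties receive
#' their average rank). The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom for
#' `n > 10`; for `n <= 10` an exact permutation test enumerates all `n!`
#' pairings (implemented in C++), which remains valid under ties.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @param exact_n maximum n for which the exact permutation p-value is
#'   used (default 10).
#' @return A list with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # rho = 0.8
#' @export
spearman_rho <- function(x, y, exact_n = 10) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: constant vector", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    p <- spearman_perm_p(rx, ry, rho)
    method <- "exact"
  } else {
    r <- min(1, max(-1, rho))
    if (abs(r) == 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}
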