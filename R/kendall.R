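# Kendall's tau-b with tie-corrected normal p-value.
#
# tau-b = S / sqrt((n0 - n1)(n0 - n2)) with S the concordant-minus-
# discordant pair count, n0 = n(n-1)/2 and n1, n2 the tied-pair counts in
# each margin.  The two-sided p-value uses the normal approximation with
# the tie-adjusted null variance of S and a continuity correction of 1 on
# the S scale.

#' Kendall's tau-b
#'
#' Tie-corrected rank correlation with a two-sided p-value from the normal
#' approximation (tie-adjusted variance, continuity correction).
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return List: `tau`, `p_value`, `n`, `S` (concordant minus discordant
#'   pairs).  When either margin is constant the correlation is undefined
#'   and `tau`/`p_value` are `NA` with a warning.
#' @examples
#' kendall_tau(1:4, c(2, 4, 6, 8))$tau   # 1
#' kendall_tau(1:4, c(8, 6, 4, 2))$tau   # -1
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y))
    stop("parameter error: x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("parameter error: need at least 2 complete pairs")

  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])

  n0 <- n * (n - 1) / 2
  tx <- as.numeric(table(x)); tx <- tx[tx > 1]
  ty <- as.numeric(table(y)); ty <- ty[ty > 1]
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    warning("undefined correlation: at least one margin is constant")
    return(list(tau = NA_real_, p_value = NA_real_, n = n, S = S))
  }
  tau <- S / denom

  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2)
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2)) else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) {
    p <- 1
  } else {
    z <- (S - sign(S)) / sqrt(var_s)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(tau = tau, p_value = p, n = n, S = S)
}
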