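#' Two-sided Mann-Whitney U test with exact small-sample enumeration
#'
#' Computes the U statistic of the first sample (number of pairs with
#' `x > y`, ties counted 1/2). When both sample sizes are at most
#' `exact_max`, the null distribution is obtained by full enumeration of
#' all `choose(n + m, n)` assignments of the pooled values (exact under
#' ties); two-sided p = `min(1, 2 * min(P(U <= u), P(U >= u)))`. Otherwise
#' the normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact mode.
#' @return List `U`, `p_value`, `method` (`"exact"` or `"normal"`),
#'   `n`, `m`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  stopifnot(is.numeric(x), is.numeric(y))
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks; U = ranksum - n(n+1)/2 counts ties as 1/2
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n <= exact_max && m <= exact_max) {
    idx <- combn(n + m, n)
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_le <- mean(Us <= U + eps)
    p_ge <- mean(Us >= U - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    list(U = U, p_value = p, method = "exact", n = n, m = m)
  } else {
    N <- n + m
    mu <- n * m / 2
    ties <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal",
                                 n = n, m = m))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(U = U, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal", n = n, m = m)
  }
}
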