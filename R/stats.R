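# The two significance tests used by the decision rules, exactly testable at
# small n.  Two-sided p-values throughout; p is floored at machine epsilon
# and formatted as "<1e-15" rather than 0.

#' Mann-Whitney U test
#'
#' U = sum over pairs of \[x_i > y_j\] + 1/2 \[x_i = y_j\].  Exact two-sided p
#' by enumeration of all rank splits when n_x + n_y <= 12 (or when forced),
#' otherwise a normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U`, `p.value` and `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (mode == "exact" || (mode == "auto" && N <= 12)) {
    sets <- combn(N, m)
    us <- apply(sets, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- m * n / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) return(list(U = u, p.value = 1, method = "normal"))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
    method <- "normal"
  }
  list(U = u, p.value = max(min(p, 1), .Machine$double.eps), method = method)
}

#' Two-proportion z-test (pooled variance)
#'
#' @param k1,n1 successes and size of the first group.
#' @param k2,n2 successes and size of the second group.
#' @return list with `z` and two-sided `p.value`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("0 <= k <= n required")
  p_pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (k1 / n1 - k2 / n2) / se
  p <- 2 * pnorm(-abs(z))
  list(z = z, p.value = max(min(p, 1), .Machine$double.eps))
}

#' Format a p-value, displaying extreme values as a bound
#' @param p numeric p-value.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-15, "<1e-15", formatC(p, format = "g", digits = 3))
}
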