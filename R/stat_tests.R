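# Self-contained exact statistical machinery used across the pipeline.
# Implemented from first principles with fully specified conventions
# (point-probability two-sided Fisher rule; exact Mann-Whitney by complete
# enumeration for small samples; tie-corrected Kruskal-Wallis; step-up BH).

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the point-probability ("minimum likelihood") rule:
#' the sum of hypergeometric point probabilities of all tables with the same
#' margins whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7). The odds ratio reported is the
#' sample odds ratio ad/bc (`Inf` or 0 at zero cells, `NaN` when undefined).
#' Tables with an empty row or column margin are degenerate and return p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return A `TestResult` list: `statistic` (odds ratio), `p`, `method`,
#'   `exact`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  or <- (a * d) / (b * c)
  m <- a + b        # row 1 margin
  n <- c + d        # row 2 margin
  k <- a + c        # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(test_result(or, 1, "fisher_exact", TRUE))
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result(or, min(1, p), "fisher_exact", TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: q_(i) = min over j >= i of
#' p_(j) * n / j, capped at 1 and mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in \[0,1\] (`NA` passed through).
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  n <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (n > 0) {
    o <- order(p)
    q <- pmin(1, cummin(rev(p[o] * n / seq_len(n))))
    q <- rev(q)
    res <- numeric(n)
    res[o] <- q
    out[ok] <- res
  }
  out
}

#' Mann-Whitney U test
#'
#' U counts pairs with x > y (ties contribute 1/2). For combined sample size
#' at most `exact_limit` the two-sided p-value is computed by complete
#' enumeration of all group assignments of the pooled values:
#' p = P(|U* - nx ny / 2| >= |U - nx ny / 2|). Larger samples use the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_limit Maximum nx + ny for exact enumeration (default 12).
#' @return A `TestResult` list: `statistic` (U for the first group), `p`,
#'   `method`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  u_of <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  u <- u_of(x, y)
  mu <- nx * ny / 2
  if (nx + ny <= exact_limit) {
    pooled <- c(x, y)
    combs <- utils::combn(nx + ny, nx)
    dev <- abs(u - mu)
    hits <- 0L
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      up <- u_of(pooled[sel], pooled[-sel])
      if (abs(up - mu) >= dev - 1e-9) hits <- hits + 1L
    }
    p <- hits / ncol(combs)
    return(test_result(u, p, "mann_whitney_exact", TRUE))
  }
  N <- nx + ny
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(nx * ny / 12 * (N + 1 - tie_term))
  if (sigma == 0) return(test_result(u, 1, "mann_whitney_normal", FALSE))
  z <- (abs(u - mu) - 0.5) / sigma
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(-z))
  test_result(u, p, "mann_whitney_normal", FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A `TestResult` list: `statistic` (H), `p`, `method`, `exact`,
#'   plus `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n_i <- lengths(groups)
  h <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) h <- h / corr
  df <- length(groups) - 1
  p <- if (h == 0) 1 else stats::pchisq(h, df, lower.tail = FALSE)
  out <- test_result(h, p, "kruskal_wallis", FALSE)
  out$df <- df
  out
}

#' @keywords internal
test_result <- function(statistic, p, method, exact) {
  structure(list(statistic = statistic, p = p, method = method, exact = exact),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p, if (x$exact) " (exact)" else ""))
  invisible(x)
}
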