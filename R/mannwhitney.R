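#' Mann-Whitney U test with exact small-sample p-values
#'
#' Two-sided, two-sample nonparametric location test. The statistic is
#' `U = #{(i, j): x_i > y_j}` with half-counts for ties. For tie-free data
#' the exact null distribution of U over all `choose(n1 + n2, n1)` equally
#' likely group assignments is computed by the standard counting recursion,
#' and the two-sided p-value is `min(1, 2 * one-sided tail)` at the observed
#' U. With ties (or on request) a normal approximation with midranks, tie
#' correction and continuity correction is used instead, as exact enumeration
#' assumes a tie-free sample.
#'
#' @param x,y numeric samples (both nonempty).
#' @param mode `"auto"` (exact when tie-free and `n1 + n2 <= 20`), `"exact"`,
#'   or `"approx"`.
#' @return A list of class `mw_test`: `u` (U for `x` over `y`), `p`
#'   (two-sided), `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # = #{x_i > y_j} (+1/2 per tie)

  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = !ties && (n1 + n2) <= 20L)
  if (use_exact && ties) use_exact <- FALSE

  if (use_exact) {
    dist <- mw_exact_distribution(n1, n2)      # counts for U = 0..n1*n2
    total <- sum(dist)
    k <- as.integer(round(u))
    lower <- sum(dist[seq_len(k + 1L)]) / total        # P(U <= u)
    upper <- sum(dist[(k + 1L):length(dist)]) / total  # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tab <- table(pooled)
    tiecorr <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr)
    if (sigma2 <= 0) return(structure(list(u = u, p = 1, n1 = n1, n2 = n2,
                                           method = "approx"),
                                      class = "mw_test"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "approx"
  }
  structure(list(u = u, p = p, n1 = n1, n2 = n2, method = method),
            class = "mw_test")
}

# Number of group assignments giving each U value, via the classical
# partition-count recursion: N(u; n1, n2) as polynomial coefficients of the
# Gaussian binomial [n1 + n2 choose n1]_q.
mw_exact_distribution <- function(n1, n2) {
  # coefficients of prod_{i=1..n1} (1 - q^(n2+i)) / (1 - q^i)
  umax <- n1 * n2
  coef <- c(1, numeric(umax))
  # multiply by 1/(1 - q^i): cumulative sums with lag i
  # multiply by (1 - q^(n2+i)): subtraction with lag n2+i
  for (i in seq_len(n1)) {
    for (u in seq.int(i, umax)) coef[u + 1] <- coef[u + 1] + coef[u + 1 - i]
    lag <- n2 + i
    if (lag <= umax)
      for (u in seq.int(umax, lag)) coef[u + 1] <- coef[u + 1] - coef[u + 1 - lag]
  }
  coef
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %.1f (n1 = %d, n2 = %d), two-sided p = %.4g\n",
              x$method, x$u, x$n1, x$n2, x$p))
  invisible(x)
}

#' Bonferroni correction
#'
#' Adjusts raw p-values for a family of `m` serial tests:
#' `p_adjusted = min(1, m * p_raw)`.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param m family size (>= 1).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m) {
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop("family size m must be a single value >= 1")
  pmin(1, m * p)
}

#' Significance star coding
#'
#' The figure-caption convention: `p <= 0.05` "*", `p <= 0.01` "**",
#' `p <= 0.001` "***", otherwise "".
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
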