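#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank transforms of `x` and `y` (ties
#' receive the mean of the ranks they span). This is the statistic used to
#' compare two scoring workflows image-by-image: monotone agreement gives
#' r = 1 regardless of calibration differences between raters.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' spearman_cor(c(1, 2, 3, 5), c(10, 20, 25, 90))  # 1: monotone
spearman_cor <- function(x, y) {
  bs_check(is.numeric(x) && is.numeric(y) && length(x) == length(y),
           "validation", "x and y must be numeric vectors of equal length")
  bs_check(length(x) >= 3L, "validation", "need at least 3 pairs")
  bs_check(all(is.finite(x)) && all(is.finite(y)), "validation", "inputs must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    bs_abort("undefined_correlation",
             "correlation undefined: at least one input is constant")
  }
  # Pearson product-moment on the ranks, written out.
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

# U statistic for sample a against sample b: number of (a_i, b_j) pairs with
# a_i > b_j, ties counting one half.
u_stat <- function(a, b) {
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  sum(cmp)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a location difference between two independent
#' samples. For small problems (`n_a + n_b <= exact_limit`, default 12) the
#' null distribution of U is built by full enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings of the pooled data — exact even
#' under ties — and the two-sided p-value is the probability of a U at least
#' as far from its null mean `n_a n_b / 2` as the observed one. Larger
#' problems use the normal approximation with the tie-corrected variance and
#' a continuity correction.
#'
#' @param a,b numeric samples (each non-empty).
#' @param exact_limit largest pooled size for the enumeration branch.
#' @return list with `U` (for sample `a`), `p` (two-sided), and
#'   `method` (`"exact_enumeration"` or `"normal_approximation"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney <- function(a, b, exact_limit = 12L) {
  bs_check(is.numeric(a) && length(a) >= 1L && all(is.finite(a)),
           "validation", "sample a must be non-empty and finite")
  bs_check(is.numeric(b) && length(b) >= 1L && all(is.finite(b)),
           "validation", "sample b must be non-empty and finite")
  na <- length(a); nb <- length(b); n <- na + nb
  u_obs <- u_stat(a, b)
  mu <- na * nb / 2

  if (n <= exact_limit) {
    pooled <- c(a, b)
    idx <- utils::combn(n, na)
    us <- apply(idx, 2, function(sel) u_stat(pooled[sel], pooled[-sel]))
    eps <- sqrt(.Machine$double.eps)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - eps)
    return(list(U = u_obs, p = p, method = "exact_enumeration"))
  }

  ranks <- rank(c(a, b))
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u_obs, p = 1, method = "normal_approximation"))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = u_obs, p = p, method = "normal_approximation")
}
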