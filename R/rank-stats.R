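#' Spearman rank correlation with a t-approximation p-value
#'
#' Self-contained implementation: ties receive average ranks, rho is the
#' Pearson correlation of the rank vectors, and the two-sided p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value in either vector are dropped (and counted).
#' `|rho| = 1` is reported with p = 0 and `degenerate = TRUE`.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p`, `n_used`, `n_dropped`, `degenerate`.
#' @export
spearman_rho <- function(x, y) {
  .assert(length(x) == length(y), "x and y must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  .assert(n >= 3, "need >= 3 complete pairs (have ", n, ")")
  .assert(length(unique(x)) > 1 && length(unique(y)) > 1,
          "rho is undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  rho <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  degenerate <- abs(rho) >= 1 - 1e-12
  p <- if (degenerate) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n_used = n, n_dropped = n_dropped,
       degenerate = degenerate)
}

#' Wilcoxon rank-sum (Mann-Whitney) test, two-sided
#'
#' Self-contained implementation. The statistic is the Mann-Whitney U of the
#' first group (rank sum minus `n_a (n_a + 1) / 2`, average ranks for ties).
#' When both groups have at most 10 observations the null distribution is
#' obtained by exact enumeration of all group splits of the observed pooled
#' values (a conditional permutation test, which handles ties exactly);
#' otherwise the normal approximation with tie correction and a continuity
#' correction is used. The two-sided p is
#' `P(|U - n_a n_b / 2| >= |u_obs - n_a n_b / 2|)`, making the test symmetric
#' under swapping the groups.
#'
#' @param a,b Numeric vectors (both non-empty, combined n >= 3).
#' @param exact_max Per-group size up to which exact enumeration is used.
#' @return List with `statistic` (U of group a), `p`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 10) {
  a <- as.numeric(a); b <- as.numeric(b)
  .assert(length(a) >= 1 && length(b) >= 1, "both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  .assert(N >= 3, "combined n must be >= 3")
  .assert(all(is.finite(c(a, b))), "non-finite values")
  r <- rank(c(a, b), ties.method = "average")
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  EU <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    splits <- utils::combn(N, na)
    Us <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - EU) >= abs(U - EU) - 1e-9)
    method <- "exact enumeration"
  } else {
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # all values tied: no evidence either way
      p <- 1
    } else {
      z <- U - EU
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(statistic = U, p = p, method = method)
}
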