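#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two degree multisets by rank. In `auto` mode the exact null
#' distribution of the Mann-Whitney U statistic is used when both samples
#' have at most 12 observations and the pooled data are untied; otherwise a
#' normal approximation with midranks, tie-corrected variance and continuity
#' correction is used. `exact` mode forces exact computation (untied data
#' only); `normal` forces the approximation.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list of class `htest` with elements `statistic` (U for `x`),
#'   `p.value`, `alternative`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L

  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for x

  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = n1 <= 12L && n2 <= 12L && !ties)
  if (exact && ties)
    warning("ties present; exact p-value uses midranks against the ",
            "tie-free null distribution", call. = FALSE)

  if (exact) {
    # with midranks U can be half-integer; bracket it
    p_le <- stats::pwilcox(floor(U + 1e-9), n1, n2)                # P(U <= u)
    p_ge <- 1 - stats::pwilcox(ceiling(U - 1e-9) - 1, n1, n2)      # P(U >= u)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      cc <- 0.5  # continuity correction
      z_ge <- (U - mu - cc) / sqrt(sigma2)
      z_le <- (U - mu + cc) / sqrt(sigma2)
      p <- switch(alternative,
                  greater = stats::pnorm(z_ge, lower.tail = FALSE),
                  less = stats::pnorm(z_le),
                  two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                             stats::pnorm(z_ge, lower.tail = FALSE))))
    }
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }

  structure(
    list(statistic = c(U = U), p.value = p, alternative = alternative,
         method = method,
         data.name = paste0("x (n=", n1, ") vs y (n=", n2, ")")),
    class = "htest"
  )
}

#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Tests association in the table `n, N-n, r, R-r`, where `n` of `N` links
#' fall in a category for one subgroup and `r` of `R` for the other. The
#' two-sided p-value follows the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' point probability does not exceed that of the observed table (within
#' relative tolerance 1e-7).
#'
#' @param n,N,r,R non-negative counts with `n <= N`, `r <= R`, `N + R >= 1`.
#'   Vectors are recycled to a common length.
#' @return numeric vector of p-values.
#' @examples
#' fisher_exact_2x2(74, 638, 5, 258)  # 3.94e-7
#' @export
fisher_exact_2x2 <- function(n, N, r, R) {
  len <- max(length(n), length(N), length(r), length(R))
  n <- rep_len(as.numeric(n), len); N <- rep_len(as.numeric(N), len)
  r <- rep_len(as.numeric(r), len); R <- rep_len(as.numeric(R), len)
  if (any(n < 0 | r < 0 | n > N | r > R))
    stop("counts must satisfy 0 <= n <= N and 0 <= r <= R")
  if (any(N + R < 1)) stop("N + R must be at least 1")

  vapply(seq_len(len), function(i) {
    K <- n[i] + r[i]
    lo <- max(0, K - R[i]); hi <- min(K, N[i])
    support <- lo:hi
    probs <- stats::dhyper(support, N[i], R[i], K)
    p_obs <- probs[n[i] - lo + 1]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni correction
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m family size (number of tests), at least 1.
#' @return `min(1, p * m)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  p <- as.numeric(p)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be a single integer >= 1")
  pmin(1, p * m)
}
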