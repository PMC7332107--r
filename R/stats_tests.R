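mx_test_result <- function(method, statistic, p_value, n1, n2 = NA_integer_,
                           ...) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         n1 = n1, n2 = n2, ...)
}

# Kolmogorov-Smirnov tail probability Q_KS(lambda) = 2 sum (-1)^(j-1)
# exp(-2 j^2 lambda^2).
q_ks <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  terms <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
  min(1, max(0, sum(terms)))
}

#' Two-dimensional two-sample Kolmogorov-Smirnov test
#'
#' The Fasano-Franceschini variant: the statistic D is the average, over
#' the two samples, of the maximum difference in quadrant occupation
#' fractions when the plane is divided at each of that sample's data
#' points; points on a dividing line are split evenly. The p-value uses
#' the asymptotic Kolmogorov distribution with the correlation correction
#' `sqrt(1 - rho^2)`,
#' `lambda = sqrt(n) D / (1 + sqrt(1 - r^2) (0.25 - 0.75 / sqrt(n)))`
#' with `n = n1 n2 / (n1 + n2)` and `r^2` the mean squared Pearson
#' correlation of the two samples. It makes no assumption about the shape
#' of the underlying distribution.
#'
#' @param sample_a,sample_b Two-column matrices or data frames of points.
#' @return One-row tibble: `method`, `statistic` (D), `p_value`, `n1`,
#'   `n2`.
#' @export
#' @examples
#' a <- cbind(rnorm(50), rnorm(50))
#' ks2d_test(a, a)$statistic  # 0
ks2d_test <- function(sample_a, sample_b) {
  a <- as.matrix(sample_a)
  b <- as.matrix(sample_b)
  if (ncol(a) != 2 || ncol(b) != 2) abort("samples must be 2-column")
  if (nrow(a) < 10 || nrow(b) < 10)
    abort("each sample must contain at least 10 points")
  if (nrow(unique(a)) == 1 || nrow(unique(b)) == 1)
    abort("degenerate sample: all points identical")
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  D <- .Call("mxpol_ks2d_d", a[, 1], a[, 2], b[, 1], b[, 2],
             PACKAGE = "mxpolarity")
  n1 <- nrow(a); n2 <- nrow(b)
  n <- n1 * n2 / (n1 + n2)
  safe_cor <- function(m) {
    r <- suppressWarnings(cor(m[, 1], m[, 2]))
    if (is.na(r)) 0 else r
  }
  r2 <- (safe_cor(a)^2 + safe_cor(b)^2) / 2
  lambda <- sqrt(n) * D / (1 + sqrt(1 - r2) * (0.25 - 0.75 / sqrt(n)))
  mx_test_result("2-D two-sample KS (Fasano-Franceschini)", D,
                 q_ks(lambda), n1, n2)
}

#' Welch's t-test with bootstrap validation
#'
#' `welch_t_test()` wraps the unequal-variance t-test with Satterthwaite
#' degrees of freedom. `bootstrap_welch_p()` estimates the two-sided
#' p-value by resampling under the null (both samples recentred to the
#' pooled mean) and comparing the resampled Welch statistics with the
#' observed one; similar magnitudes of analytic and bootstrap p-values
#' support the normal-approximation assumption.
#'
#' @param x,y Numeric samples (>= 2 values each, not both constant).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return One-row tibble (see [ks2d_test()]) with an added `df` column;
#'   `bootstrap_welch_p()` returns a scalar p-value.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 values per sample")
  if (sd(x) == 0 && sd(y) == 0) abort("both samples have zero variance")
  if (identical(sort(x), sort(y)))
    return(mx_test_result("Welch two-sample t", 0, 1, length(x), length(y),
                          df = length(x) + length(y) - 2))
  ht <- t.test(x, y)
  mx_test_result("Welch two-sample t", unname(ht$statistic), ht$p.value,
                 length(x), length(y), df = unname(ht$parameter))
}

#' @rdname welch_t_test
#' @export
bootstrap_welch_p <- function(x, y, n_boot = 1000, seed = 1) {
  welch_stat <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  obs <- welch_stat(x, y)
  mu <- mean(c(x, y))
  x0 <- x - mean(x) + mu
  y0 <- y - mean(y) + mu
  with_seed(seed, {
    stats <- vapply(seq_len(n_boot), function(i) {
      welch_stat(sample(x0, replace = TRUE), sample(y0, replace = TRUE))
    }, numeric(1))
    (1 + sum(abs(stats) >= abs(obs))) / (n_boot + 1)
  })
}

#' Exact binomial test
#'
#' Exact tail probabilities for `k` successes in `n` trials against success
#' probability `p0`; the two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (the standard exact
#' two-sided rule, as used for old/new and leading/lagging pole bias with
#' `p0 = 0.5`).
#'
#' @param k Successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @param sided `"two"` (default), `"greater"` or `"less"`.
#' @return One-row tibble with `statistic` = observed proportion.
#' @export
#' @examples
#' binomial_test(5, 10)$p_value  # 1
binomial_test <- function(k, n, p0 = 0.5, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[sided]]
  ht <- binom.test(k, n, p = p0, alternative = alt)
  mx_test_result(paste0("exact binomial (", sided, "-sided)"),
                 k / n, ht$p.value, n)
}

#' Chi-squared test for independence
#'
#' Pearson's chi-squared statistic with `(r - 1)(c - 1)` degrees of freedom
#' and no continuity correction. Warns when any expected count is 5 or
#' below (the usual validity guard); errors on a zero row or column
#' marginal.
#'
#' @param table Counts matrix (2 x 2 or larger).
#' @return One-row tibble with `df` and `n1` = total count.
#' @export
#' @examples
#' chi2_independence(matrix(c(50, 10, 10, 50), 2))
chi2_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("zero marginal in contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5))
    warn("some expected counts are <= 5; the chi-squared approximation may be poor")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  mx_test_result("Pearson chi-squared independence",
                 unname(ht$statistic), ht$p.value, sum(tab),
                 df = unname(ht$parameter))
}
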