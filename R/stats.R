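#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of independence in a 2x2 contingency table using the
#' point-probability ("at least as unlikely") convention: the two-sided p
#' is the sum of hypergeometric point probabilities, over all tables with
#' the observed margins, that do not exceed the probability of the
#' observed table. This is the convention used for the cohort age by
#' SMARCB1-status comparisons.
#'
#' Probabilities are evaluated in log space via [stats::dhyper()] for
#' numerical stability; a relative tolerance of 1e-7 guards against
#' floating-point ties when comparing point probabilities.
#'
#' @param tab 2x2 integer matrix (or vector of length 4, row-major
#'   `c(a, b, c, d)`), all entries non-negative, total > 0. Rows index one
#'   factor (e.g. age group), columns the other (e.g. SMARCB1 negative /
#'   positive).
#' @return A `test_result` list: `statistic` (the odds ratio estimate
#'   `ad/bc`, possibly `Inf`), `p`, `method`, `n` (per-row totals).
#' @examples
#' fisher_exact_two_sided(matrix(c(4, 1, 9, 27), nrow = 2))$p
#' @export
fisher_exact_two_sided <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (!is.matrix(tab) || any(dim(tab) != 2L)) {
    stop("`tab` must be a 2x2 matrix or a length-4 vector")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  if (sum(tab) == 0) stop("all-zero table: no observations to test")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- stats::dhyper(support, r1, r2, c1, log = TRUE)
  obs <- logp[support == a]
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  test_result(statistic = or, p = min(p, 1), method = "fisher_exact_two_sided",
              n = c(row1 = r1, row2 = r2))
}

#' Exact two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' For combined sample sizes up to `exact_limit` the permutation
#' distribution of the rank-sum is computed exactly by dynamic programming
#' over all `choose(n1 + n2, n1)` group reassignments, using mid-ranks for
#' ties (ranks are doubled internally so tied mid-ranks stay integral).
#' The two-sided p is the proportion of reassignments whose U statistic
#' deviates from its null mean by at least the observed deviation. Larger
#' samples fall back to the tie-corrected normal approximation with
#' continuity correction.
#'
#' This is the test used for ROI cell-count comparisons, where four
#' regions per group make exact enumeration essential: the minimal
#' attainable two-sided p at n = 4 vs 4 is 2/70 = 0.0286.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_limit combined-size cutoff for exact enumeration
#'   (default 30).
#' @return A `test_result` list with `statistic` (U for the `x` sample),
#'   `p`, `method` (`"mann_whitney_exact"` or `"mann_whitney_normal"`),
#'   and `n`.
#' @examples
#' mann_whitney_exact_two_sided(1:4, 5:8)$p  # 2/70
#' @export
mann_whitney_exact_two_sided <- function(x, y, exact_limit = 30L) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))           # mid-ranks for ties
  w <- sum(r[seq_len(n1)])     # rank-sum of x
  u <- w - n1 * (n1 + 1) / 2
  eu <- n1 * n2 / 2
  dev <- abs(u - eu)
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
    counts <- rank_sum_distribution(r2, n1)
    total <- choose(n, n1)
    # U in doubled units: 2w - n1(n1+1); deviation threshold likewise doubled
    sums <- as.numeric(names(counts))
    u2 <- sums - n1 * (n1 + 1)
    hits <- sum(counts[abs(u2 - n1 * n2) >= 2 * dev - 1e-9])
    p <- hits / total
    method <- "mann_whitney_exact"
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (dev - 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "mann_whitney_normal"
  }
  test_result(statistic = u, p = p, method = method, n = c(n1 = n1, n2 = n2))
}

# Exact distribution of the sum of a size-n1 subset of the (integer) vector
# `v`: generating-function DP returning counts named by achievable sums.
rank_sum_distribution <- function(v, n1) {
  max_sum <- sum(sort(v, decreasing = TRUE)[seq_len(n1)])
  # dp[k+1, s+1] = number of k-subsets with sum s
  dp <- matrix(0, nrow = n1 + 1, ncol = max_sum + 1)
  dp[1, 1] <- 1
  for (val in v) {
    kmax <- n1
    for (k in seq.int(kmax, 1)) {
      nz <- which(dp[k, ] > 0)
      nz <- nz[nz + val <= max_sum + 1]
      if (length(nz)) dp[k + 1, nz + val] <- dp[k + 1, nz + val] + dp[k, nz]
    }
  }
  counts <- dp[n1 + 1, ]
  keep <- counts > 0
  stats::setNames(counts[keep], which(keep) - 1L)
}

#' Two-sample or paired Student t-test
#'
#' Pooled-variance (Student) two-sample t-test, or the paired mean-difference
#' test when `paired = TRUE`. The pooled form is the per-CpG test of the
#' differential-methylation stage; the paired form serves replicate growth
#' comparisons. When the pooled variance is exactly zero, p is 1 by
#' convention if the means are equal and 0 otherwise.
#'
#' @param x,y numeric vectors with at least 2 observations each; equal
#'   lengths required when `paired = TRUE`.
#' @param paired logical.
#' @return A `test_result` list with `statistic` (t), `p`, `df`, `method`,
#'   `n`.
#' @export
t_test_two_sample <- function(x, y, paired = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample")
  if (paired) {
    if (n1 != n2) stop("paired test requires equal-length samples")
    d <- x - y
    df <- n1 - 1
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      tstat <- mean(d) / (sd_d / sqrt(n1))
    }
    method <- "t_paired"
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
    if (sp2 == 0) {
      tstat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    } else {
      tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
    method <- "t_student_pooled"
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  out <- test_result(statistic = tstat, p = p, method = method,
                     n = c(n1 = n1, n2 = n2))
  out$df <- df
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min over j >= i of
#' m * p_(j) / j, capped at 1, in the original input order.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed; returned
#'   as NA and excluded from m).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / seq.int(m, 1) * pv[o]))[ro]
  q
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items from a
#' universe of `N` of which `K` are marked, the probability of at least
#' `k` marked draws. Evaluated through [stats::phyper()] (log-space
#' stable). This is the enrichment p-value of over-representation and
#' metaprogram-overlap scoring.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K marked items in the universe.
#' @param n draws (query size).
#' @param N universe size.
#' @return upper-tail probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric arguments: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Wald test for an age effect in a binomial GLM
#'
#' Fits status ~ age by binomial logistic regression (IRLS via
#' [stats::glm()], convergence epsilon 1e-8) and reports the slope with
#' its two-sided Wald p. Complete or quasi-complete separation is detected
#' (fitted probabilities collapsing to 0/1 with a diverging slope) and
#' flagged: the result then carries `separation = TRUE`, `p = NA`, and a
#' warning, rather than a spurious p-value.
#'
#' @param age numeric covariate.
#' @param status binary response (0/1 or logical), both classes present,
#'   n >= 4.
#' @return A `test_result` list with `statistic` (Wald z), `p`,
#'   `estimate` (slope), `se`, `separation`, `n`.
#' @export
logistic_wald <- function(age, status) {
  status <- as.integer(status)
  if (length(age) != length(status)) stop("age and status lengths differ")
  if (length(age) < 4) stop("need n >= 4")
  if (length(unique(status)) < 2) stop("both status classes must be present")
  fit <- suppressWarnings(
    stats::glm(status ~ age, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  mu <- stats::fitted(fit)
  slope <- stats::coef(fit)[["age"]]
  se <- sqrt(stats::vcov(fit)["age", "age"])
  eps <- 1e-8
  separated <- !fit$converged || all(mu < eps | mu > 1 - eps) || abs(slope) > 50
  if (separated) {
    warning("complete or quasi-complete separation: slope diverges, p not reported")
    out <- test_result(statistic = NA_real_, p = NA_real_,
                       method = "logistic_wald", n = length(age))
  } else {
    z <- slope / se
    out <- test_result(statistic = z, p = 2 * stats::pnorm(-abs(z)),
                       method = "logistic_wald", n = length(age))
  }
  out$estimate <- slope
  out$se <- se
  out$separation <- separated
  out
}

# Shared lightweight result container.
test_result <- function(statistic, p, method, n) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(statistic = statistic, p = p, method = method, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p, digits = 4),
      ", n = ", paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}
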