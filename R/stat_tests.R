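# The 11 statistical criteria evaluated on each (feature, activity) pair:
# five correlation tests (significance is favourable) and six
# regression-applicability diagnostics (a significant departure is
# unfavourable). Each returns a significance level alpha in (0, 1],
# floored at 1e-10 so the log-scale utility mapping stays finite.

.ALPHA_FLOOR <- 1e-10

.clip_alpha <- function(a) pmin(1, pmax(.ALPHA_FLOOR, a))

.test_result <- function(id, statistic, alpha, direction) {
  structure(list(criterion = id, statistic = statistic,
                 alpha = .clip_alpha(alpha), direction = direction),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, alpha = %.4g (%s)\n",
              x$criterion, x$statistic, x$alpha, x$direction))
  invisible(x)
}

# ---- correlation tests (direction: favourable) -------------------------

.pearson_alpha <- function(x, y) {
  n <- length(x)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(c(0, 1))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(c(r, .ALPHA_FLOOR))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r, 2 * stats::pt(-abs(t), n - 2))
}

#' Correlation tests with significance levels
#'
#' `cor_test_pearson()` is the linear (product-moment) correlation with the
#' two-sided t test on `n - 2` df; `cor_test_spearman()` is Spearman's rank
#' correlation (average ranks for ties) with the same t approximation on
#' rho; `cor_test_kendall()` is Kendall's tau-b with the normal
#' approximation on the concordance score. Constant input is defined as
#' zero correlation with `alpha = 1`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return A `test_result` with fields `criterion`, `statistic`, `alpha`,
#'   `direction`.
#' @export
cor_test_pearson <- function(x, y) {
  .check_xy(x, y, 3L)
  pa <- .pearson_alpha(x, y)
  .test_result("pearson", pa[1], pa[2], "favourable")
}

#' @rdname cor_test_pearson
#' @export
cor_test_spearman <- function(x, y) {
  .check_xy(x, y, 3L)
  pa <- .pearson_alpha(rank(x), rank(y))
  .test_result("spearman", pa[1], pa[2], "favourable")
}

#' @rdname cor_test_pearson
#' @export
cor_test_kendall <- function(x, y) {
  .check_xy(x, y, 3L)
  n <- length(x)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  t1 <- n0 - sum(dx[up] != 0)
  t2 <- n0 - sum(dy[up] != 0)
  if (t1 == n0 || t2 == n0) return(.test_result("kendall", 0, 1, "favourable"))
  tau <- s / sqrt((n0 - t1) * (n0 - t2))
  z <- s / sqrt(n * (n - 1) * (2 * n + 5) / 18)
  alpha <- if (abs(tau) >= 1) .ALPHA_FLOOR else 2 * stats::pnorm(-abs(z))
  .test_result("kendall", tau, alpha, "favourable")
}

#' Dichotomous (median-split) association tests
#'
#' Both variables are split at their median (strictly above the median is
#' "high"; ties at the median go low) and the resulting 2x2 table is
#' tested by the chi-square test without continuity correction (df = 1)
#' and by the two-sided Fisher exact test (probability-ordering rule, the
#' convention of [stats::fisher.test()]). A degenerate margin (an empty
#' row or column) gives `alpha = 1` for both.
#'
#' @inheritParams cor_test_pearson
#' @return List with elements `chi2` and `fisher`, each a `test_result`.
#' @export
dichotomous_tests <- function(x, y) {
  .check_xy(x, y, 4L)
  hx <- x > stats::median(x)
  hy <- y > stats::median(y)
  tab <- table(factor(hx, c(FALSE, TRUE)), factor(hy, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = .test_result("chi2", 0, 1, "favourable"),
                fisher = .test_result("fisher", 1, 1, "favourable")))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  chi2 <- .test_result("chi2", stat, stats::pchisq(stat, 1, lower.tail = FALSE),
                       "favourable")
  fisher <- .test_result("fisher", tab[2, 2], .fisher2x2(tab), "favourable")
  list(chi2 = chi2, fisher = fisher)
}

# two-sided Fisher exact p for a 2x2 table: sum of hypergeometric
# probabilities not exceeding the observed table's probability
.fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 2])
  lo <- max(0L, k - m); hi <- min(nn, k)
  supp <- lo:hi
  p <- stats::dhyper(supp, nn, m, k)
  obs <- stats::dhyper(tab[2, 2], nn, m, k)
  sum(p[p <= obs * (1 + 1e-7)])
}

# ---- regression-applicability diagnostics (direction: unfavourable) ----

# KS-type test against Uniform(min, max) with range estimated from data
.unif_alpha <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(1)
  suppressWarnings(stats::ks.test(v, "punif", rng[1], rng[2])$p.value)
}

# Lilliefors-type KS against Normal(mean, sd) estimated from the residuals
.norm_alpha <- function(res) {
  s <- stats::sd(res)
  if (s < 1e-12 * max(1, max(abs(res)))) return(1)
  suppressWarnings(stats::ks.test(res, "pnorm", mean(res), s)$p.value)
}

# Wald-Wolfowitz runs test on residual signs, normal approximation.
# Zero residuals are dropped; fewer than 2 of either sign -> alpha 1.
.runs_alpha <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 2) return(1)
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' The six regression-applicability criteria
#'
#' Diagnostics of whether ordinary linear regression between an activity
#' vector `x` and a feature vector `f` is applicable: (1) uniformity of
#' `x` over its range, (2) uniformity of `f`, (3) normality and (4)
#' independence (runs test ordered by `x`) of the residuals of the
#' feature-on-activity regression, and (5)-(6) the same for the
#' activity-on-feature regression. All six carry
#' `direction = "unfavourable"`: a small alpha flags a violated
#' assumption. Uniformity/normality use KS-type tests with parameters
#' estimated from the data; zero-variance residuals (a perfect fit) pass
#' with `alpha = 1`.
#'
#' @param x Activity vector.
#' @param f Feature vector, same length (`n >= 5`).
#' @return List of 6 `test_result`s named `unif_x`, `unif_f`, `norm_fx`,
#'   `indep_fx`, `norm_xf`, `indep_xf`.
#' @export
applicability_criteria <- function(x, f) {
  .check_xy(x, f, 5L)
  res_fx <- .ols_residuals(x, f)   # f on x  (lambda, mu)
  res_xf <- .ols_residuals(f, x)   # x on f  (phi, psi)
  ord_x <- order(x, seq_along(x))
  ord_f <- order(f, seq_along(f))
  list(
    unif_x = .test_result("unif_x", NA_real_, .unif_alpha(x), "unfavourable"),
    unif_f = .test_result("unif_f", NA_real_, .unif_alpha(f), "unfavourable"),
    norm_fx = .test_result("norm_fx", NA_real_, .norm_alpha(res_fx), "unfavourable"),
    indep_fx = .test_result("indep_fx", NA_real_, .runs_alpha(res_fx[ord_x]),
                            "unfavourable"),
    norm_xf = .test_result("norm_xf", NA_real_, .norm_alpha(res_xf), "unfavourable"),
    indep_xf = .test_result("indep_xf", NA_real_, .runs_alpha(res_xf[ord_f]),
                            "unfavourable")
  )
}

# residuals of y regressed on x (closed-form simple least squares);
# constant regressor -> residuals about the mean
.ols_residuals <- function(x, y) {
  vx <- stats::var(x)
  if (vx == 0) return(y - mean(y))
  b <- stats::cov(x, y) / vx
  a <- mean(y) - b * mean(x)
  y - (a + b * x)
}

.check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < min_n) stop("need at least ", min_n, " observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  invisible(TRUE)
}

#' All 11 criteria on one (activity, feature) pair
#'
#' Convenience wrapper returning the five correlation tests and six
#' applicability diagnostics in the stable criterion order used by the
#' search engine. On subsets too small for a given test the test returns
#' `alpha = 1` instead of erroring (degenerate-input convention, so the
#' engine can score half-splits of small datasets).
#'
#' @param x Activity vector.
#' @param f Feature vector.
#' @return Named list of 11 `test_result`s.
#' @export
all_criteria <- function(x, f) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  res <- list(
    pearson = safe(cor_test_pearson(x, f)),
    spearman = safe(cor_test_spearman(x, f)),
    kendall = safe(cor_test_kendall(x, f))
  )
  dt <- safe(dichotomous_tests(x, f))
  res$chi2 <- dt$chi2; res$fisher <- dt$fisher
  ac <- safe(applicability_criteria(x, f))
  for (nm in c("unif_x", "unif_f", "norm_fx", "indep_fx", "norm_xf", "indep_xf"))
    res[[nm]] <- ac[[nm]]
  dirs <- c(rep("favourable", 5), rep("unfavourable", 6))
  nms <- c("pearson", "spearman", "kendall", "chi2", "fisher",
           "unif_x", "unif_f", "norm_fx", "indep_fx", "norm_xf", "indep_xf")
  out <- vector("list", 11); names(out) <- nms
  for (i in seq_along(nms)) {
    out[[i]] <- if (is.null(res[[nms[i]]]))
      .test_result(nms[i], NA_real_, 1, dirs[i]) else res[[nms[i]]]
  }
  out
}
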