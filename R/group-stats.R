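#' Significance stars for a p-value
#'
#' `p < 0.05` one star, `p < 0.01` two, `p < 0.001` three; otherwise empty.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, "")
}

comparison_result <- function(test, statistic, p_value, n_a, n_b, extra = list()) {
  out <- c(list(test = test, statistic = statistic,
                p_value = min(1, p_value), n_a = n_a, n_b = n_b,
                stars = significance_stars(min(1, p_value))), extra)
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s (n = %d vs %d)\n",
              x$test, x$statistic, x$p_value, x$stars, x$n_a, x$n_b))
  invisible(x)
}

# U statistic of sample a (midranks handle ties)
u_statistic <- function(ranks_a, n_a) sum(ranks_a) - n_a * (n_a + 1) / 2

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (both groups of size at most
#' `exact_max`) the null distribution of U is obtained by exhaustive
#' enumeration of all group assignments of the pooled values (valid under
#' ties), with p = 2 * min(P(U <= u), P(U >= u)) capped at 1. Larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric samples.
#' @param exact_max largest group size for the exact path (default 8).
#' @return a `comparison_result` (fields `test`, `statistic` = U of `a`,
#'   `p_value`, `n_a`, `n_b`, `stars`, `exact`).
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- u_statistic(rk[seq_len(n1)], n1)
  exact <- n1 <= exact_max && n2 <= exact_max
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  comparison_result("Mann-Whitney U", u, p, n1, n2, extra = list(exact = exact))
}

#' Welch two-sample t test
#'
#' Unpaired t test with Welch correction (Satterthwaite degrees of freedom).
#' When both groups have zero variance, p is 1 for equal means and 0
#' otherwise (degenerate convention).
#'
#' @param a,b numeric samples (at least 2 values each).
#' @return a `comparison_result` with extra fields `df`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("both samples need >= 2 values")
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(comparison_result("Welch t", if (equal) 0 else Inf,
                             if (equal) 1 else 0, n1, n2,
                             extra = list(df = NA_real_,
                                          mean_a = mean(a), mean_b = mean(b))))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  comparison_result("Welch t", t_stat, p, n1, n2,
                    extra = list(df = df, mean_a = mean(a), mean_b = mean(b)))
}

#' Two-way ANOVA with interaction (type-II sums of squares)
#'
#' Fits `value ~ A * B` and computes type-II tests, appropriate for the
#' unbalanced day-by-species designs of maturation studies.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced).
#' @param names labels for the two factors in the output.
#' @return data.frame of class `anova_result`: `factor`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          names = c("A", "B")) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("each factor needs >= 2 levels")
  d <- data.frame(y = values, A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("aliased factors: design does not support the interaction model")
  at <- car::Anova(fit, type = 2)
  df2 <- at["Residuals", "Df"]
  rows <- c("A", "B", "A:B")
  out <- data.frame(
    factor = c(names, paste(names, collapse = ":")),
    F = at[rows, "F value"],
    df1 = at[rows, "Df"],
    df2 = df2,
    p = at[rows, "Pr(>F)"],
    row.names = NULL)
  class(out) <- c("anova_result", class(out))
  out
}

#' Shapiro-Wilk normality screen
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list: `W`, `p`, `n`.
#' @export
shapiro_screen <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro screen requires 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("constant sample: normality screen undefined")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value, n = length(x))
}
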