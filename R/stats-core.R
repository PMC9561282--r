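#' One-sided Mann-Whitney (unpaired Wilcoxon) rank-sum test
#'
#' The statistic is \eqn{U = \#\{(i, j): x_i > y_j\}} with ties counted 1/2
#' (equivalently the rank-sum form with midranks). `direction = "less"` tests
#' the alternative that `x` is stochastically smaller than `y` (small U
#' extreme); `"greater"` tests the opposite tail. The p-value is computed by
#' full enumeration of all \eqn{\binom{n_x + n_y}{n_x}} group assignments when
#' the combined sample size is at most `exact_cutoff` and the pooled data are
#' tie-free; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param direction `"less"` or `"greater"`.
#' @param exact_cutoff Combined-n ceiling for exact enumeration (default 12).
#' @param force One of `"auto"`, `"exact"`, `"approx"` — mainly for verifying
#'   the approximation against the exact tail.
#' @return A `driploop_htest`: statistic `U`, `p.value`, `alternative`,
#'   sample sizes and a method flag (`"exact"` / `"normal approximation"`).
#' @export
#' @examples
#' wilcoxon_one_sided(c(1, 2, 3), c(4, 5, 6), "less")$p.value  # 1/20
wilcoxon_one_sided <- function(x, y, direction = c("less", "greater"),
                               exact_cutoff = 12, force = c("auto", "exact", "approx")) {
  direction <- rlang::arg_match(direction)
  force <- rlang::arg_match(force)
  if (length(x) < 1L || length(y) < 1L) abort("Both samples must be non-empty.")
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L

  # U for x via midranks: U = R_x - nx(nx+1)/2 counts pairs x_i > y_j (+1/2 ties)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  use_exact <- switch(force,
    exact = TRUE,
    approx = FALSE,
    auto = n <= exact_cutoff && !ties
  )

  if (use_exact) {
    p <- exact_u_tail(pooled, nx, U, direction)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else if (direction == "less") {
      p <- pnorm((U - mu + 0.5) / sigma)
    } else {
      p <- 1 - pnorm((U - mu - 0.5) / sigma)
    }
    method <- "normal approximation"
  }

  new_htest(
    statistic = c(U = U),
    p.value = min(max(p, 0), 1),
    alternative = direction,
    method = method,
    test = "Mann-Whitney rank-sum",
    n = c(n_x = nx, n_y = ny)
  )
}

# Exact tail probability of U by enumerating every assignment of nx pooled
# values to the first group. Inclusive tails (P(U <= u) / P(U >= u)).
exact_u_tail <- function(pooled, nx, u_obs, direction) {
  r <- rank(pooled)
  combos <- combn(length(pooled), nx)
  offset <- nx * (nx + 1) / 2
  us <- colSums(matrix(r[combos], nrow = nx)) - offset
  tol <- 1e-9
  if (direction == "less") {
    mean(us <= u_obs + tol)
  } else {
    mean(us >= u_obs - tol)
  }
}

#' Pearson correlation test
#'
#' \eqn{r = \sum (x - \bar x)(y - \bar y) / \sqrt{\sum (x - \bar x)^2
#' \sum (y - \bar y)^2}}, with the two-sided p-value from
#' \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} on \eqn{n - 2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @return A `driploop_htest` with `estimate` r, statistic t, df and p.value.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("Need n >= 3 finite pairs.")
  sx <- x - mean(x); sy <- y - mean(y)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) abort("Zero variance in `x` or `y`: correlation undefined.")
  r <- sum(sx * sy) / den
  r <- min(max(r, -1), 1)
  df <- n - 2
  if (abs(r) == 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t), df)
  }
  new_htest(
    statistic = c(t = t),
    estimate = c(r = r),
    parameter = df,
    p.value = p,
    alternative = "two.sided",
    method = "exact",
    test = "Pearson correlation",
    n = c(n = n)
  )
}

#' Paired t-test
#'
#' \eqn{t = \bar d / (s_d / \sqrt n)} on the per-pair differences
#' \eqn{d = a - b}, with \eqn{n - 1} degrees of freedom. Two-sided by default.
#'
#' @param a,b Paired numeric vectors of equal length n >= 2.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for `a - b`).
#' @return A `driploop_htest` with statistic t, df, `estimate` (mean
#'   difference) and p.value.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- rlang::arg_match(alternative)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2L) abort("Need at least 2 pairs.")
  if (anyNA(a) || anyNA(b)) abort("Samples must not contain NA.")
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      # a == b exactly: no evidence of a shift
      return(new_htest(
        statistic = c(t = 0), parameter = n - 1, p.value = 1,
        estimate = c(mean_difference = 0),
        alternative = alternative, method = "exact", test = "paired t",
        n = c(n_pairs = n)
      ))
    }
    abort("All differences identical and non-zero: sd is 0, t undefined.")
  }
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(t), df),
    less = pt(t, df),
    greater = 1 - pt(t, df)
  )
  new_htest(
    statistic = c(t = t),
    parameter = df,
    estimate = c(mean_difference = mean(d)),
    p.value = p,
    alternative = alternative,
    method = "exact",
    test = "paired t",
    n = c(n_pairs = n)
  )
}

new_htest <- function(statistic, p.value, alternative, method, test, n,
                      estimate = NULL, parameter = NULL) {
  structure(
    list(
      statistic = statistic,
      estimate = estimate,
      parameter = parameter,
      p.value = p.value,
      alternative = alternative,
      method = method,
      test = test,
      n = n
    ),
    class = "driploop_htest"
  )
}

#' @export
print.driploop_htest <- function(x, ...) {
  cat("<", x$test, "> (", x$method, ")\n", sep = "")
  cat("  ", names(x$statistic)[1], " = ", format(x$statistic[1]), sep = "")
  if (!is.null(x$parameter)) cat(", df =", x$parameter)
  cat(", p =", format.pval(x$p.value), "\n")
  if (!is.null(x$estimate)) {
    cat("  ", names(x$estimate)[1], "=", format(x$estimate[1]), "\n")
  }
  cat("  alternative:", x$alternative, "; n:",
      paste(names(x$n), x$n, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
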