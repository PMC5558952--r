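#' Cox-Stuart sign test for monotonic trend
#'
#' Splits the series in half (dropping the middle element when the length
#' is odd), pairs each value of the first half with its counterpart
#' `floor(n/2)` positions later, and counts positive pair differences.
#' Under the no-trend null the count of positive signs is
#' Binomial(m, 1/2) over the m untied pairs; the p-value is the exact
#' binomial tail (no normal approximation), two-sided by default.
#'
#' If every pair is tied the test is degenerate: p = 1, direction
#' `"none"`, and `degenerate = TRUE`.
#'
#' @param x Numeric series (length >= 4).
#' @param alternative `"two_sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return An object of class `trend_result`: a list with `n_pairs_used`
#'   (untied pairs m), `s_plus`, `p_value`, `direction` (`"increasing"`,
#'   `"decreasing"` or `"none"`), `alternative`, `degenerate`.
#' @examples
#' cox_stuart(1:20, alternative = "increasing")  # p = 0.5^10
#' @export
cox_stuart <- function(x, alternative = c("two_sided", "increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("cox_stuart: series must have length >= 4")
  c_ <- n %/% 2L
  if (n %% 2L == 1L) x <- x[-(c_ + 1L)]         # drop middle element
  d <- x[(c_ + 1L):(2L * c_)] - x[1:c_]
  d <- d[d != 0]                                 # discard tied pairs
  m <- length(d)
  s_plus <- sum(d > 0)
  if (m == 0L) {
    res <- list(n_pairs_used = 0L, s_plus = 0L, p_value = 1,
                direction = "none", alternative = alternative,
                degenerate = TRUE)
    class(res) <- "trend_result"
    return(res)
  }
  p_up <- stats::pbinom(s_plus - 1L, m, 0.5, lower.tail = FALSE)  # P(S >= s_plus)
  p_down <- stats::pbinom(s_plus, m, 0.5)                         # P(S <= s_plus)
  p <- switch(alternative,
              increasing = p_up,
              decreasing = p_down,
              two_sided = min(1, 2 * min(p_up, p_down)))
  direction <- if (s_plus > m / 2) "increasing"
  else if (s_plus < m / 2) "decreasing" else "none"
  res <- list(n_pairs_used = m, s_plus = s_plus, p_value = p,
              direction = direction, alternative = alternative,
              degenerate = FALSE)
  class(res) <- "trend_result"
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Cox-Stuart trend test (%s): S+ = %d of %d pairs, p = %.4g, direction: %s\n",
              x$alternative, x$s_plus, x$n_pairs_used, x$p_value, x$direction))
  invisible(x)
}

#' Pettitt change-point test
#'
#' Tests for a single shift in the central tendency of a series.  The
#' statistic at split point t is the signed Mann-Whitney-type double sum
#' \deqn{U_t = \sum_{i \le t} \sum_{j > t} \mathrm{sgn}(x_i - x_j),}
#' computed here in O(T log T) via midranks (ties contribute 0 through the
#' sign).  K is the maximum of |U_t|, tau the split at which it occurs
#' (the earliest, on ties), and the significance uses the standard
#' closed-form approximation
#' `p = 2 exp(-6 K^2 / (T^3 + T^2))`, capped at 1.
#'
#' @param x Numeric series (length >= 8).
#' @return An object of class `changepoint_result`: list with `U_t`
#'   (length T-1), `K`, `tau`, `p_approx`, `n`.
#' @export
pettitt <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("pettitt: series must have length >= 8")
  r <- rank(x, ties.method = "average")
  # sum_{j != i} sgn(x_i - x_j) = 2 r_i - (n + 1); within-segment terms cancel
  U <- cumsum(2 * r - (n + 1))[seq_len(n - 1L)]
  K <- max(abs(U))
  tau <- which.max(abs(U))
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  res <- list(U_t = U, K = K, tau = tau, p_approx = p, n = n)
  class(res) <- "changepoint_result"
  res
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("Pettitt change-point test: K = %g at tau = %d (n = %d), approx p = %.4g\n",
              x$K, x$tau, x$n, x$p_approx))
  invisible(x)
}

#' Dunn's test for multiple pairwise rank comparisons
#'
#' Nonparametric post-hoc comparisons between k groups after a joint
#' midrank ranking of all N values.  For groups a, b the standardized
#' rank-mean difference is
#' \deqn{z_{ab} = \frac{\bar R_a - \bar R_b}
#'   {\sqrt{\left[\frac{N(N+1)}{12} - \frac{\sum(t^3 - t)}{12(N-1)}\right]
#'    \left(\frac{1}{n_a} + \frac{1}{n_b}\right)}}}
#' with the usual tie correction over tie groups of size t.  Two-sided
#' normal p-values; optional Holm step-down adjustment across the
#' k(k-1)/2 comparisons.
#'
#' @param groups Named list of numeric vectors (k >= 2, all non-empty),
#'   or a numeric vector with `g` a grouping factor.
#' @param g Optional grouping vector when `groups` is a numeric vector.
#' @param adjustment `"none"` (default) or `"holm"`.
#' @return Data frame with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adjusted`, `method`.
#' @export
dunn_test <- function(groups, g = NULL, adjustment = c("none", "holm")) {
  adjustment <- match.arg(adjustment)
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (!is.list(groups) || length(groups) < 2L)
    stop("dunn_test: need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("dunn_test: all groups must be non-empty")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (length(unique(x)) == 1L)
    stop("dunn_test: degenerate ranking (all values identical)")
  lab <- rep(names(groups), vapply(groups, length, integer(1)))
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, lab, mean)
  nn <- tapply(r, lab, length)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2L)
  z <- apply(pairs, 2L, function(p)
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(v0 * (1 / nn[[p[1]]] + 1 / nn[[p[2]]])))
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjustment == "holm") stats::p.adjust(p_raw, "holm") else p_raw
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
             p_raw = p_raw, p_adjusted = p_adj, method = adjustment,
             stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation with t-approximation p-value
#'
#' Thin wrapper around the standard product-moment correlation reporting
#' r, r^2 and the two-sided p-value from `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-zero variance.
#' @return List with `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_correlation: lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson_correlation: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = n)
}

#' One-way ANOVA with Holm-adjusted pairwise t-tests (pooled SD)
#'
#' Classical one-way analysis of variance across species (or any grouping),
#' followed by all pairwise t-tests that use the pooled within-group
#' standard deviation from *all* groups, with Holm step-down adjustment of
#' the pairwise p-values.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (coerced to factor).
#' @return List with `anova` (data frame: `df_between`, `df_within`, `F`,
#'   `p_value`) and `pairwise` (data frame: `group_a`, `group_b`,
#'   `p_adjusted`, method `"holm"`).
#' @export
compare_species <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("compare_species: excluding group(s) with < 2 values: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    values <- values[keep]; group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L)
    stop("compare_species: need at least 2 groups with >= 2 values each")
  fit <- stats::aov(values ~ group)
  at <- summary(fit)[[1]]
  an <- data.frame(df_between = at$Df[1], df_within = at$Df[2],
                   F = at$`F value`[1], p_value = at$`Pr(>F)`[1])
  pt <- stats::pairwise.t.test(values, group, p.adjust.method = "holm",
                               pool.sd = TRUE)
  pm <- pt$p.value
  rows <- do.call(rbind, lapply(rownames(pm), function(a)
    do.call(rbind, lapply(colnames(pm), function(b) {
      p <- pm[a, b]
      if (is.na(p)) NULL
      else data.frame(group_a = b, group_b = a, p_adjusted = p,
                      method = "holm", stringsAsFactors = FALSE)
    }))))
  list(anova = an, pairwise = rows)
}
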