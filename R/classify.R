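#' Configuration for the growth-pattern classifier
#'
#' @param alpha Significance level for the embedded Cox-Stuart tests
#'   (default 0.05).
#' @param window Odd moving-average window in years applied before
#'   classification (default 11).
#' @param depression_factor A depression year is one where the smoothed
#'   series falls below this fraction of its running maximum (default 0.8).
#' @param depression_min_years Minimum consecutive depression years for a
#'   dip to count (default 15).
#' @param min_length Minimum series length for classification (default 40;
#'   the archetypes are lifetime-scale patterns and are meaningless on
#'   short series).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(alpha = 0.05, window = 11,
                              depression_factor = 0.8,
                              depression_min_years = 15,
                              min_length = 40) {
  stopifnot(alpha > 0, alpha < 1, window >= 1, window %% 2 == 1,
            depression_factor > 0, depression_factor < 1,
            depression_min_years >= 1, min_length >= 8)
  structure(list(alpha = alpha, window = window,
                 depression_factor = depression_factor,
                 depression_min_years = depression_min_years,
                 min_length = min_length),
            class = "classifier_config")
}

#' The four canonical lifetime growth archetypes
#'
#' @return Character vector of the four labels, in classifier priority
#'   order: `rise_then_decline`, `increase_with_depression`,
#'   `sustained_increase`, `plateau`.
#' @export
growth_archetypes <- function() {
  c("rise_then_decline", "increase_with_depression",
    "sustained_increase", "plateau")
}

#' Classify a lifetime growth series into one of four archetypes
#'
#' Applies a deterministic decision rule to the moving-average-smoothed
#' series m(t):
#' \enumerate{
#'   \item \strong{rise_then_decline} if the Cox-Stuart test on the second
#'     half of m is significantly decreasing;
#'   \item else \strong{increase_with_depression} if the Cox-Stuart test on
#'     the full m is significantly increasing \emph{and} m dips below
#'     `depression_factor` times its running maximum for at least
#'     `depression_min_years` consecutive years and later recovers above
#'     the pre-dip maximum;
#'   \item else \strong{sustained_increase} if the full-series Cox-Stuart
#'     test is significantly increasing;
#'   \item else \strong{plateau}.
#' }
#' All ingredients are sign/rank based or relative, so the label is
#' invariant to positive rescaling of the series.
#'
#' @param x Numeric lifetime series (annual increments such as ring widths
#'   or annual carbon accumulation), length >= `config$min_length`.
#' @param config A [classifier_config()].
#' @param tree_id Optional identifier carried into the result.
#' @return An object of class `pattern_label`: list with `tree_id`,
#'   `label`, and `evidence` (full-series and second-half trend results
#'   plus the depression descriptor).
#' @export
classify_pattern <- function(x, config = classifier_config(),
                             tree_id = NA_character_) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.numeric(x)
  n <- length(x)
  if (n < config$min_length)
    stop(sprintf("classify_pattern: series length %d < minimum %d",
                 n, config$min_length))
  m <- moving_average(x, config$window)

  second_half <- m[(n %/% 2 + 1L):n]
  cs_late <- cox_stuart(second_half, alternative = "decreasing")
  cs_full <- cox_stuart(m, alternative = "two_sided")
  dep <- find_depression(m, config$depression_factor,
                         config$depression_min_years)

  increasing <- !cs_full$degenerate && cs_full$p_value <= config$alpha &&
    cs_full$direction == "increasing"
  label <-
    if (!cs_late$degenerate && cs_late$p_value <= config$alpha)
      "rise_then_decline"
    else if (increasing && dep$found) "increase_with_depression"
    else if (increasing) "sustained_increase"
    else "plateau"

  structure(list(tree_id = tree_id, label = label,
                 evidence = list(trend_full = cs_full,
                                 trend_second_half = cs_late,
                                 depression = dep)),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("<pattern_label> %s: %s (full-trend p = %.3g, late-decline p = %.3g, depression: %s)\n",
              x$tree_id, x$label, x$evidence$trend_full$p_value,
              x$evidence$trend_second_half$p_value,
              if (x$evidence$depression$found) "yes" else "no"))
  invisible(x)
}

# Locate the first qualifying growth depression in a smoothed series.
# A depression episode is a maximal run of years spent below the running
# maximum held at its entry (the pre-dip high watermark).  It qualifies if
# it lasts at least min_years, dips below factor * the pre-dip maximum at
# some point, and is followed by recovery above that maximum.
find_depression <- function(m, factor, min_years) {
  runmax <- cummax(m)
  below <- m < runmax           # below the high watermark so far
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_years)
  for (k in cand) {
    s <- starts[k]; e <- ends[k]
    pre_max <- runmax[s]        # running max frozen at dip entry
    deep <- min(m[s:e]) < factor * pre_max
    recovered <- e < length(m) && any(m[(e + 1L):length(m)] > pre_max)
    if (deep && recovered)
      return(list(found = TRUE, start = s, end = e,
                  depth = 1 - min(m[s:e]) / pre_max))
  }
  list(found = FALSE, start = NA_integer_, end = NA_integer_,
       depth = NA_real_)
}
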