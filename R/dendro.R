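#' Mean tree-ring series across radii
#'
#' Averages two or more cross-dated radii of one tree into a single mean
#' ring-width series.  All radii must already be aligned at the outermost
#' ring (equal `last_year`) and have equal ring counts; no realignment is
#' attempted here — cross-dating is assumed done upstream and can be
#' checked with [crossdate_check()].
#'
#' A zero width marks a wedge (locally absent) ring: it is excluded from
#' that year's mean rather than averaged in as zero growth, because the
#' tree did grow that year elsewhere on the circumference.  Only if every
#' radius records 0 in a year is the mean 0 (a truly missing ring).
#'
#' @param radii List of at least two [ring_series()] for one tree.
#' @return A [ring_series()] with `radius_id = "mean"`.
#' @export
mean_tree_series <- function(radii) {
  if (!is.list(radii) || length(radii) < 2L)
    stop("mean_tree_series: need at least 2 radii; got ",
         if (is.list(radii)) length(radii) else 1L)
  stopifnot(all(vapply(radii, inherits, logical(1), "ring_series")))
  n <- vapply(radii, length, integer(1))
  if (length(unique(n)) != 1L)
    stop("mean_tree_series: radii have unequal ring counts (",
         paste(n, collapse = ", "),
         "); cross-date and align the radii before averaging")
  ly <- vapply(radii, `[[`, integer(1), "last_year")
  if (length(unique(ly)) != 1L)
    stop("mean_tree_series: radii are not aligned at the outermost ring; ",
         "last years differ (", paste(ly, collapse = ", "), ")")
  w <- do.call(rbind, lapply(radii, `[[`, "widths"))  # radii x years
  present <- w > 0
  sums <- colSums(w)
  k <- colSums(present)
  m <- ifelse(k > 0, sums / pmax(k, 1L), 0)
  ring_series(tree_id = radii[[1]]$tree_id, radius_id = "mean",
              widths = m, last_year = radii[[1]]$last_year,
              species = radii[[1]]$species,
              resolution_mm = radii[[1]]$resolution_mm)
}

#' Pairwise cross-dating coherence of radii
#'
#' Reports, for every pair of radii of one tree, the Pearson correlation of
#' first-differenced log ring widths — the classic high-frequency signal
#' used to judge whether radii record the same year-to-year growth pattern.
#' Wedge years (width 0 on either radius of the pair, in either year of the
#' difference) are skipped pairwise.  No realignment is performed; pairs
#' below `threshold` are flagged for manual inspection, and series shorter
#' than 10 rings are flagged `"too short"` with no correlation computed.
#'
#' @param radii List of [ring_series()] aligned at the outermost ring.
#' @param threshold Flag pairs whose correlation falls below this value
#'   (default 0.3).
#' @return A data frame with one row per radius pair: `radius_a`,
#'   `radius_b`, `n_years` (differences used), `correlation`, `flag`.
#' @export
crossdate_check <- function(radii, threshold = 0.3) {
  stopifnot(is.list(radii), length(radii) >= 2L,
            all(vapply(radii, inherits, logical(1), "ring_series")))
  ly <- vapply(radii, `[[`, integer(1), "last_year")
  if (length(unique(ly)) != 1L)
    stop("crossdate_check: radii are not aligned at the outermost ring")
  ids <- vapply(radii, `[[`, character(1), "radius_id")
  dlog <- lapply(radii, function(s) {
    w <- s$widths
    lw <- ifelse(w > 0, log(w), NA_real_)
    diff(lw)
  })
  pairs <- utils::combn(length(radii), 2L)
  res <- apply(pairs, 2L, function(p) {
    a <- dlog[[p[1]]]; b <- dlog[[p[2]]]
    if (length(radii[[p[1]]]) < 10L || length(radii[[p[2]]]) < 10L)
      return(list(ids[p[1]], ids[p[2]], 0L, NA_real_, "too short"))
    ok <- is.finite(a) & is.finite(b)
    # pad to common length defensively; equal lengths are the usual case
    n <- min(length(a), length(b))
    ok <- ok[seq_len(n)]
    if (sum(ok) < 3L)
      return(list(ids[p[1]], ids[p[2]], sum(ok), NA_real_, "too short"))
    r <- stats::cor(a[seq_len(n)][ok], b[seq_len(n)][ok])
    flag <- if (!is.finite(r)) "degenerate" else if (r < threshold) "low correlation" else ""
    list(ids[p[1]], ids[p[2]], sum(ok), r, flag)
  })
  data.frame(
    radius_a = vapply(res, `[[`, character(1), 1L),
    radius_b = vapply(res, `[[`, character(1), 2L),
    n_years = vapply(res, function(x) as.integer(x[[3]]), integer(1)),
    correlation = vapply(res, function(x) as.numeric(x[[4]]), numeric(1)),
    flag = vapply(res, `[[`, character(1), 5L),
    stringsAsFactors = FALSE)
}

#' Reconstruct the diameter trajectory from a mean ring series
#'
#' The under-bark diameter at year t is twice the cumulative mean ring
#' width up to t (mm converted to cm); the annual diameter increment is
#' twice the ring width.  No pith-offset or bark correction is applied, so
#' the reconstruction is conservative for biomass purposes.
#'
#' @param mean_series A [ring_series()], normally from [mean_tree_series()].
#' @return A data frame of class `diameter_trajectory` with columns
#'   `tree_id`, `year`, `age` (cambial age 1..T), `diameter_cm`
#'   (non-decreasing), `increment_cm`.
#' @export
reconstruct_diameter <- function(mean_series) {
  stopifnot(inherits(mean_series, "ring_series"))
  w <- mean_series$widths
  inc <- 2 * w / 10          # mm radius increment -> cm diameter increment
  d <- cumsum(inc)
  out <- data.frame(
    tree_id = mean_series$tree_id,
    year = seq(first_year(mean_series), mean_series$last_year),
    age = seq_along(w),
    diameter_cm = d,
    increment_cm = inc,
    stringsAsFactors = FALSE)
  class(out) <- c("diameter_trajectory", "data.frame")
  out
}

#' Centered moving average with shrinking edges
#'
#' Smooths a series with a centered window of odd width.  At the edges the
#' window shrinks symmetrically-as-possible (it is truncated at the series
#' boundary), so the output has the same length as the input and no years
#' are dropped or padded.
#'
#' @param x Numeric vector or [ring_series()].
#' @param window Odd integer window width in years (>= 1).
#' @return Smoothed numeric vector (or `ring_series` if given one).
#' @export
moving_average <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window))
    stop("moving_average: 'window' must be a positive integer")
  if (window %% 2 == 0)
    stop("moving_average: 'window' must be odd for a centered mean")
  if (inherits(x, "ring_series")) {
    y <- x
    y$widths <- moving_average(x$widths, window)
    return(y)
  }
  n <- length(x)
  h <- (window - 1L) / 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}
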