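#' Published species-level statistics of the Suriname reference cohort
#'
#' Species-level summary statistics reported for the 61-tree reference
#' cohort of Cedrela odorata, Goupia glabra and Hymenaea courbaril from
#' unmanaged Suriname wet forest: tree counts, lifetime age and final
#' diameter (mean/min/max), final carbon stock (kg, mean/min/max), pooled
#' annual carbon accumulation and annual diameter growth statistics, and
#' the mean percent of lifetime carbon accumulated in each lifetime
#' quarter.  The raw ring measurements behind these summaries were never
#' deposited, so these numbers serve as the calibration envelope for the
#' synthetic cohort generator and as an internal-consistency reference
#' (e.g. mean diameter over mean age against printed mean annual growth).
#'
#' @return A list of data frames `stock`, `annual` and `quartiles` with
#'   the same schemas as [cohort_summary()].
#' @export
reference_cohort_stats <- function() {
  stock <- data.frame(
    species = c("C.odorata", "G.glabra", "H.courbaril"),
    n_trees = c(20L, 21L, 20L),
    age_mean = c(138, 149, 155),
    age_min = c(84, 112, 87),
    age_max = c(180, 189, 255),
    diameter_mean = c(52.3, 54.4, 67.8),
    diameter_min = c(36.7, 40.3, 40.8),
    diameter_max = c(64.9, 75.8, 99.2),
    carbon_mean = c(819, 1685, 3157),
    carbon_min = c(329, 772, 849),
    carbon_max = c(1320, 3523, 7319),
    stringsAsFactors = FALSE)
  annual <- data.frame(
    species = c("C.odorata", "G.glabra", "H.courbaril"),
    annual_c_mean = c(6.0, 12.2, 20.3),
    annual_c_min = c(0.0, 0.0, 0.0),
    annual_c_max = c(44.1, 186.1, 215.3),
    annual_c_sd = c(6.1, 13.2, 21.6),
    diameter_growth_mean = c(0.38, 0.37, 0.44),
    diameter_growth_min = c(0.04, 0.11, 0.04),
    diameter_growth_max = c(2.51, 2.64, 1.98),
    diameter_growth_sd = c(0.28, 0.17, 0.29),
    stringsAsFactors = FALSE)
  quartiles <- data.frame(
    species = rep(c("C.odorata", "G.glabra", "H.courbaril"), each = 4L),
    quarter = rep(1:4, times = 3L),
    share_mean = c(8.0, 23.0, 30.4, 38.6,
                   3.6, 16.3, 29.9, 50.2,
                   5.1, 19.3, 33.2, 42.4),
    share_min = c(1.6, 9.4, 22.3, 18.5,
                  1.6, 8.2, 10.7, 38.9,
                  0.3, 3.6, 18.6, 18.2),
    share_max = c(19.0, 39.1, 37.8, 63.5,
                  6.4, 23.1, 40.3, 77.8,
                  23.6, 34.4, 41.3, 76.8),
    stringsAsFactors = FALSE)
  list(stock = stock, annual = annual, quartiles = quartiles)
}
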