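#' Pantropical aboveground biomass allometry
#'
#' Estimates aboveground biomass (kg dry mass) of a tropical tree from its
#' trunk-base diameter D (cm), wood density rho (g cm^-3) and a site-level
#' environmental stress factor E, using the pantropical height-free model
#'
#' \deqn{AGB = \exp\{-1.803 - 0.976E + 0.976\ln\rho + 2.673\ln D
#'       - 0.0339[\ln D]^2\}}
#'
#' E grows with temperature seasonality and water deficit, so AGB decreases
#' with E at fixed size; it increases with D and rho.  D = 0 is mapped to
#' AGB 0 (the limit convention), so full lifetime trajectories may start at
#' the pith year; negative diameters are an error.
#'
#' @param D Diameter in cm (vectorised, >= 0).
#' @param rho Wood density in g cm^-3 (> 0).
#' @param E Environmental stress factor (dimensionless, default 0).
#' @return AGB in kg, same length as the broadcast of the inputs.
#' @examples
#' agb_chave(50, rho = 0.77, E = 0)   # ~2.6 tonnes
#' @export
agb_chave <- function(D, rho, E = 0) {
  if (any(!is.finite(D)) || any(D < 0))
    stop("agb_chave: D must be finite and >= 0")
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("agb_chave: rho must be > 0")
  out <- rep(0, length.out = max(length(D), length(rho), length(E)))
  D2 <- rep_len(D, length(out))
  pos <- D2 > 0
  lnD <- log(D2[pos])
  out[pos] <- exp(-1.803 - 0.976 * rep_len(E, length(out))[pos] +
                    0.976 * log(rep_len(rho, length(out))[pos]) +
                    2.673 * lnD - 0.0339 * lnD^2)
  out
}

#' Lifetime carbon trajectory of one tree
#'
#' Converts a diameter trajectory to per-year aboveground biomass, carbon
#' stock and annual carbon accumulation.  Carbon stock is
#' `carbon_fraction * AGB`; annual accumulation is the first difference of
#' the carbon stock, with the first year's accumulation equal to the first
#' year's stock (the trajectory starts from a zero origin at the pith).
#' The accumulation series therefore telescopes exactly to the final stock.
#'
#' @param traj A `diameter_trajectory` from [reconstruct_diameter()].
#' @param rho Wood density in g cm^-3.
#' @param E Environmental stress factor.
#' @param carbon_fraction Biomass-to-carbon fraction in (0,1).
#' @return A data frame of class `carbon_trajectory` with columns
#'   `tree_id`, `year`, `age`, `diameter_cm`, `agb_kg`, `carbon_kg`,
#'   `annual_c_kg`.
#' @export
carbon_trajectory <- function(traj, rho, E = 0, carbon_fraction = 0.471) {
  stopifnot(inherits(traj, "diameter_trajectory") ||
              all(c("tree_id", "year", "diameter_cm") %in% names(traj)))
  if (!is.numeric(carbon_fraction) || carbon_fraction <= 0 || carbon_fraction >= 1)
    stop("carbon_trajectory: carbon_fraction must lie in (0, 1)")
  agb <- agb_chave(traj$diameter_cm, rho = rho, E = E)
  carbon <- carbon_fraction * agb
  annual <- diff(c(0, carbon))
  out <- data.frame(
    tree_id = traj$tree_id,
    year = traj$year,
    age = if ("age" %in% names(traj)) traj$age else seq_along(agb),
    diameter_cm = traj$diameter_cm,
    agb_kg = agb,
    carbon_kg = carbon,
    annual_c_kg = annual,
    stringsAsFactors = FALSE)
  class(out) <- c("carbon_trajectory", "data.frame")
  out
}

#' Quarter index of each year of a lifetime
#'
#' Years 1..T are split at ceiling(T/4), ceiling(T/2) and ceiling(3T/4);
#' each year goes to the earliest quarter whose upper boundary it does not
#' exceed, so every year lies in exactly one quarter even when T is not
#' divisible by 4.
#'
#' @param T Lifetime length in years (integer >= 4).
#' @return Integer vector of length T with values in 1..4.
#' @export
lifetime_quarters <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || T < 4 || T != round(T))
    stop("lifetime_quarters: T must be an integer >= 4")
  bounds <- ceiling(T * (1:4) / 4)
  findInterval(seq_len(T), c(0, bounds), left.open = TRUE)
}

#' Percent of lifetime carbon accumulated per lifetime quarter
#'
#' Divides a tree's lifetime into four periods of equal length (see
#' [lifetime_quarters()]) and reports the percentage of the final carbon
#' stock accumulated in each.  Shares sum to 100 by the telescoping
#' identity of annual accumulation.
#'
#' @param traj A `carbon_trajectory` from [carbon_trajectory()].
#' @return A data frame of class `quartile_summary` with columns `tree_id`,
#'   `quarter` (1..4) and `share_percent`.
#' @export
quartile_shares <- function(traj) {
  stopifnot(all(c("tree_id", "annual_c_kg") %in% names(traj)))
  T <- nrow(traj)
  if (T < 4)
    stop("quartile_shares: lifetime must be at least 4 years, got ", T)
  q <- lifetime_quarters(T)
  total <- sum(traj$annual_c_kg)
  if (total <= 0)
    stop("quartile_shares: final carbon stock must be positive")
  sums <- vapply(1:4, function(k) sum(traj$annual_c_kg[q == k]), numeric(1))
  out <- data.frame(tree_id = traj$tree_id[1], quarter = 1:4,
                    share_percent = 100 * sums / total,
                    stringsAsFactors = FALSE)
  class(out) <- c("quartile_summary", "data.frame")
  out
}

#' Cumulative carbon curve
#'
#' The running sum of annual carbon accumulation; by construction equal to
#' the per-year carbon stock, and non-decreasing whenever ring widths are
#' non-negative.
#'
#' @param traj A `carbon_trajectory`.
#' @return Numeric vector, cumulative carbon in kg per year.
#' @export
cumulative_curve <- function(traj) {
  stopifnot("annual_c_kg" %in% names(traj))
  cumsum(traj$annual_c_kg)
}

#' Species-level cohort summary tables
#'
#' Builds the three canonical species-level summaries from per-tree results:
#' \describe{
#'   \item{`stock`}{per species: number of trees; mean/min/max of age,
#'     final diameter (cm) and final carbon stock (kg).}
#'   \item{`annual`}{per species: mean/min/max/SD of annual carbon
#'     accumulation (kg) and of annual diameter growth (cm), pooling all
#'     tree-years within a species.}
#'   \item{`quartiles`}{per species and lifetime quarter: mean/min/max of
#'     the percent carbon accumulated in that quarter.}
#' }
#'
#' @param trajectories List of `carbon_trajectory` data frames.
#' @param species Character vector, species of each trajectory.
#' @param quartiles Optional list of `quartile_summary` objects (computed
#'   from the trajectories when omitted).
#' @return A list with data frames `stock`, `annual` and `quartiles`.
#' @export
cohort_summary <- function(trajectories, species, quartiles = NULL) {
  stopifnot(length(trajectories) == length(species), length(trajectories) > 0)
  if (is.null(quartiles)) quartiles <- lapply(trajectories, quartile_shares)

  keep <- !is.na(species)
  if (any(!keep)) {
    warning("cohort_summary: dropping ", sum(!keep), " tree(s) with missing species")
    trajectories <- trajectories[keep]; quartiles <- quartiles[keep]
    species <- species[keep]
  }
  sp <- sort(unique(species))

  per_tree <- data.frame(
    species = species,
    age = vapply(trajectories, nrow, integer(1)),
    diameter_cm = vapply(trajectories, function(t) t$diameter_cm[nrow(t)], numeric(1)),
    carbon_kg = vapply(trajectories, function(t) t$carbon_kg[nrow(t)], numeric(1)),
    stringsAsFactors = FALSE)

  stock <- do.call(rbind, lapply(sp, function(s) {
    d <- per_tree[per_tree$species == s, ]
    data.frame(species = s, n_trees = nrow(d),
               age_mean = mean(d$age), age_min = min(d$age), age_max = max(d$age),
               diameter_mean = mean(d$diameter_cm), diameter_min = min(d$diameter_cm),
               diameter_max = max(d$diameter_cm),
               carbon_mean = mean(d$carbon_kg), carbon_min = min(d$carbon_kg),
               carbon_max = max(d$carbon_kg), stringsAsFactors = FALSE)
  }))

  annual <- do.call(rbind, lapply(sp, function(s) {
    idx <- which(species == s)
    cc <- unlist(lapply(trajectories[idx], `[[`, "annual_c_kg"))
    dd <- unlist(lapply(trajectories[idx], function(t)
      if ("increment_cm" %in% names(t)) t$increment_cm else diff(c(0, t$diameter_cm))))
    data.frame(species = s,
               annual_c_mean = mean(cc), annual_c_min = min(cc),
               annual_c_max = max(cc), annual_c_sd = stats::sd(cc),
               diameter_growth_mean = mean(dd), diameter_growth_min = min(dd),
               diameter_growth_max = max(dd), diameter_growth_sd = stats::sd(dd),
               stringsAsFactors = FALSE)
  }))

  qdf <- do.call(rbind, quartiles)
  qdf$species <- rep(species, each = 4L)
  qtab <- do.call(rbind, lapply(sp, function(s) {
    do.call(rbind, lapply(1:4, function(k) {
      v <- qdf$share_percent[qdf$species == s & qdf$quarter == k]
      data.frame(species = s, quarter = k, share_mean = mean(v),
                 share_min = min(v), share_max = max(v),
                 stringsAsFactors = FALSE)
    }))
  }))

  list(stock = stock, annual = annual, quartiles = qtab)
}
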