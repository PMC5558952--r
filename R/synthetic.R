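#' Parameters of one growth archetype
#'
#' Describes the deterministic mean structure and the stochastic deviation
#' law of a simulated ring-width series.  The mean structure is built from
#' a juvenile ramp (linear rise from 30% of `base_width_mm` to the full
#' base width over `juvenile_ramp_years`), an adult linear drift
#' `trend_slope`, an optional smooth multiplicative depression window, and
#' an optional late linear decline.  Deviations are multiplicative
#' lognormal with AR(1) log-deviations: ring widths are positive and
#' serially correlated, which is what the mean-corrected noise law
#' reproduces.
#'
#' @param archetype One of [growth_archetypes()].
#' @param juvenile_ramp_years Length of the juvenile ramp in years (>= 0).
#' @param base_width_mm Mean adult ring width in mm (> 0).
#' @param trend_slope Drift of the adult mean in mm/yr (>= 0; forced to 0
#'   for the plateau archetype).
#' @param depression For `increase_with_depression`: list with
#'   `start_fraction` of lifetime, `length_years`, and `depth_fraction`
#'   in (0,1); realized as a raised-cosine multiplicative dip so the edges
#'   are smooth and do not create artificial change points.
#' @param decline For `rise_then_decline`: list with `onset_fraction` of
#'   lifetime and `rate`, the relative width loss per year after onset
#'   (fraction of the onset width, so the parameter is scale-free).
#' @param ar1_phi Lag-1 autocorrelation of the log-deviations, in `[0, 1)`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (>= 0; 0 gives the deterministic mean structure).
#' @return A list of class `archetype_params`.
#' @export
archetype_params <- function(archetype = "sustained_increase",
                             juvenile_ramp_years = 15,
                             base_width_mm = 1.5,
                             trend_slope = 0.008,
                             depression = NULL,
                             decline = NULL,
                             ar1_phi = 0.3,
                             noise_cv = 0.1) {
  archetype <- match.arg(archetype, growth_archetypes())
  stopifnot(juvenile_ramp_years >= 0, base_width_mm > 0,
            ar1_phi >= 0, ar1_phi < 1, noise_cv >= 0)
  if (archetype == "plateau") trend_slope <- 0
  if (trend_slope < 0)
    stop("archetype_params: trend_slope must be >= 0 (declines are expressed via 'decline')")
  if (archetype == "increase_with_depression") {
    if (is.null(depression))
      depression <- list(start_fraction = 0.45, length_years = 30,
                         depth_fraction = 0.4)
    stopifnot(depression$start_fraction > 0, depression$start_fraction < 1,
              depression$length_years >= 1,
              depression$depth_fraction > 0, depression$depth_fraction < 1)
  } else depression <- NULL
  if (archetype == "rise_then_decline") {
    if (is.null(decline))
      decline <- list(onset_fraction = 0.5, rate = NA_real_)
    stopifnot(decline$onset_fraction > 0, decline$onset_fraction < 1)
  } else decline <- NULL
  structure(list(archetype = archetype,
                 juvenile_ramp_years = juvenile_ramp_years,
                 base_width_mm = base_width_mm,
                 trend_slope = trend_slope,
                 depression = depression,
                 decline = decline,
                 ar1_phi = ar1_phi,
                 noise_cv = noise_cv),
            class = "archetype_params")
}

#' Deterministic mean ring-width structure of an archetype
#'
#' The noiseless expected ring width for each cambial year 1..age under an
#' [archetype_params()] set.  Errors if the parameters imply a
#' non-positive expected width anywhere.
#'
#' @param params An [archetype_params()].
#' @param age Lifetime in years (>= `juvenile_ramp_years`).
#' @return Numeric vector of length `age`, strictly positive.
#' @export
archetype_mean <- function(params, age) {
  stopifnot(inherits(params, "archetype_params"))
  if (age < params$juvenile_ramp_years)
    stop("archetype_mean: age must be >= juvenile_ramp_years")
  t <- seq_len(age)
  b <- params$base_width_mm
  R <- params$juvenile_ramp_years
  mu <- ifelse(t <= R, b * (0.3 + 0.7 * t / max(R, 1L)),
               b + params$trend_slope * (t - R))
  if (!is.null(params$decline)) {
    t0 <- max(R + 1L, round(params$decline$onset_fraction * age))
    rate <- params$decline$rate
    if (is.na(rate)) rate <- 0.65 / (age - t0)   # end width = 35% of peak
    late <- t > t0
    mu[late] <- mu[t0] * (1 - rate * (t[late] - t0))
  }
  if (!is.null(params$depression)) {
    d <- params$depression
    ts <- round(d$start_fraction * age)
    u <- (t - ts) / d$length_years
    dip <- ifelse(u >= 0 & u <= 1,
                  d$depth_fraction * 0.5 * (1 - cos(2 * pi * u)), 0)
    mu <- mu * (1 - dip)
  }
  if (any(mu <= 0))
    stop("archetype_mean: parameters imply non-positive expected ring widths")
  mu
}

#' Simulate a tree-level true ring-width series
#'
#' Draws one series of length `age` from the archetype's mean structure
#' with multiplicative lognormal AR(1) deviations.  The log-deviations are
#' a stationary AR(1) process with lag-1 correlation `ar1_phi`; the
#' lognormal is mean-corrected so the expected width equals the mean
#' structure for any noise level.  With `noise_cv = 0` the mean structure
#' is returned exactly.
#'
#' @param params An [archetype_params()].
#' @param age Lifetime in years.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of `age` positive ring widths in mm.
#' @export
simulate_tree <- function(params, age, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- archetype_mean(params, age)
  cv <- params$noise_cv
  if (cv == 0) return(mu)
  sigma2 <- log(1 + cv^2)
  sigma <- sqrt(sigma2)
  phi <- params$ar1_phi
  e <- numeric(age)
  e[1] <- stats::rnorm(1, 0, sigma)
  if (age > 1) {
    innov <- stats::rnorm(age - 1L, 0, sigma * sqrt(1 - phi^2))
    for (t in 2:age) e[t] <- phi * e[t - 1L] + innov[t - 1L]
  }
  mu * exp(e - sigma2 / 2)
}

#' Realize measured radii from a true ring-width series
#'
#' Turns one tree-level true series into `radii_per_tree` measured radii:
#' each radius multiplies every ring by independent lognormal noise of
#' coefficient of variation `radial_noise_cv`, wedge (locally absent)
#' rings are introduced by setting a radius-year to width 0 with
#' probability `wedge_ring_prob` — but never on all radii of the same year,
#' since a wedge ring is by definition present somewhere on the disc —
#' and widths are rounded to `resolution_mm`.
#'
#' @param true_widths Numeric vector of true ring widths in mm.
#' @param radii_per_tree Number of radii (>= 2).
#' @param radial_noise_cv CV of the per-ring lognormal measurement/
#'   circumference noise (>= 0).
#' @param wedge_ring_prob Per radius-year probability of a wedge ring,
#'   in `[0, 1)`.
#' @param tree_id,species,last_year Metadata for the resulting series.
#' @param resolution_mm Rounding resolution (default 0.01 mm).
#' @param seed Optional integer seed.
#' @return List of `radii_per_tree` [ring_series()] objects with radius
#'   ids `<tree_id>r1`, `<tree_id>r2`, ...
#' @export
realize_radii <- function(true_widths, radii_per_tree = 6,
                          radial_noise_cv = 0.1, wedge_ring_prob = 0.01,
                          tree_id = "T1", species = NA_character_,
                          last_year = length(true_widths),
                          resolution_mm = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (radii_per_tree < 2) stop("realize_radii: radii_per_tree must be >= 2")
  if (wedge_ring_prob >= 1 || wedge_ring_prob < 0)
    stop("realize_radii: wedge_ring_prob must lie in [0, 1)")
  n <- length(true_widths)
  sigma2 <- log(1 + radial_noise_cv^2)
  w <- matrix(0, nrow = radii_per_tree, ncol = n)
  for (k in seq_len(radii_per_tree)) {
    noise <- if (radial_noise_cv == 0) rep(1, n)
    else exp(stats::rnorm(n, -sigma2 / 2, sqrt(sigma2)))
    w[k, ] <- true_widths * noise
  }
  if (wedge_ring_prob > 0) {
    wedge <- matrix(stats::runif(radii_per_tree * n) < wedge_ring_prob,
                    nrow = radii_per_tree)
    allw <- colSums(wedge) == radii_per_tree
    wedge[1L, allw] <- FALSE        # a wedge ring is never absent everywhere
    w[wedge] <- 0
  }
  w <- round(w / resolution_mm) * resolution_mm
  lapply(seq_len(radii_per_tree), function(k)
    ring_series(tree_id = tree_id,
                radius_id = sprintf("%sr%d", tree_id, k),
                widths = w[k, ], last_year = last_year,
                species = species, resolution_mm = resolution_mm))
}

#' Cohort configuration for the synthetic forest generator
#'
#' One block per species plus cohort-wide settings.  The default
#' configuration reproduces the shape of the three-species Suriname study
#' cohort: 20 Cedrela odorata, 21 Goupia glabra and 20 Hymenaea courbaril
#' trees (61 in total), with species-wise age and final-diameter ranges
#' matching the published cohort (ages 84-255 years, diameters
#' 36.7-99.2 cm overall) and species wood densities 0.38, 0.72 and
#' 0.77 g cm^-3.
#'
#' @param species_blocks List of per-species lists with fields `species`,
#'   `n_trees`, `age_range` (2 integers), `diameter_range` (2 values, cm),
#'   `wood_density`, `archetype_weights` (named, summing to 1).
#' @param radii_per_tree Radii measured per tree (>= 2; default 6, the
#'   study-scale average of 369 radii over 61 trees).
#' @param radial_noise_cv Between-radius noise CV (default 0.1).
#' @param wedge_ring_prob Wedge-ring probability per radius-year
#'   (default 0.01).
#' @param noise_cv Tree-level ring-width noise CV (default 0.1).
#' @param ar1_phi Lag-1 autocorrelation of tree-level log-deviations
#'   (default 0.3).
#' @param stress_E Site environmental stress factor (default 0).
#' @param carbon_fraction Biomass-to-carbon fraction (default 0.471).
#' @param felling_year Common nominal felling year assigned to the
#'   outermost ring (default 2015).
#' @param seed Integer seed driving all randomness (default 1).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(species_blocks,
                          radii_per_tree = 6,
                          radial_noise_cv = 0.1,
                          wedge_ring_prob = 0.01,
                          noise_cv = 0.1,
                          ar1_phi = 0.3,
                          stress_E = 0,
                          carbon_fraction = 0.471,
                          felling_year = 2015,
                          seed = 1) {
  stopifnot(is.list(species_blocks), radii_per_tree >= 2)
  for (b in species_blocks) {
    stopifnot(all(c("species", "n_trees", "age_range", "diameter_range",
                    "wood_density", "archetype_weights") %in% names(b)))
    if (abs(sum(b$archetype_weights) - 1) > 1e-8)
      stop("cohort_config: archetype weights for ", b$species,
           " must sum to 1")
    if (!all(names(b$archetype_weights) %in% growth_archetypes()))
      stop("cohort_config: unknown archetype in weights for ", b$species)
  }
  structure(list(species_blocks = species_blocks,
                 radii_per_tree = radii_per_tree,
                 radial_noise_cv = radial_noise_cv,
                 wedge_ring_prob = wedge_ring_prob,
                 noise_cv = noise_cv,
                 ar1_phi = ar1_phi,
                 stress_E = stress_E,
                 carbon_fraction = carbon_fraction,
                 felling_year = felling_year,
                 seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param ... Overrides passed on to [cohort_config()].
#' @export
default_cohort_config <- function(...) {
  w <- c(sustained_increase = 0.60, increase_with_depression = 0.25,
         plateau = 0.07, rise_then_decline = 0.08)
  blocks <- list(
    list(species = "C.odorata", n_trees = 20, age_range = c(84, 180),
         diameter_range = c(36.7, 64.9), wood_density = 0.38,
         archetype_weights = w),
    list(species = "G.glabra", n_trees = 21, age_range = c(112, 189),
         diameter_range = c(40.3, 75.8), wood_density = 0.72,
         archetype_weights = w),
    list(species = "H.courbaril", n_trees = 20, age_range = c(87, 255),
         diameter_range = c(40.8, 99.2), wood_density = 0.77,
         archetype_weights = w))
  cohort_config(species_blocks = blocks, ...)
}

# Bisection on base_width so the deterministic mean structure sums to the
# target radius; monotone because the structure scales with the base width
# plus a base-independent drift term.
calibrate_base_width <- function(params, age, target_radius_mm,
                                 lower = 1e-3, upper = 100, tol = 1e-8) {
  f <- function(b) {
    p <- params; p$base_width_mm <- b
    sum(archetype_mean(p, age))
  }
  if (f(lower) > target_radius_mm || f(upper) < target_radius_mm)
    stop(sprintf(
      "calibrate_base_width: target radius %.1f mm unreachable at age %d with archetype '%s'",
      target_radius_mm, age, params$archetype))
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (f(mid) < target_radius_mm) lower <- mid else upper <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}

#' Simulate a synthetic tree cohort
#'
#' Generates a full multi-species cohort of [tree_record()]s from a
#' [cohort_config()], together with a ground-truth ledger (per-tree
#' archetype and parameters) and the true tree-level series, so that
#' downstream recovery can be scored exactly.  For every tree the base
#' ring width is calibrated by bisection on the deterministic mean
#' structure so that the noiseless final diameter (twice the summed ring
#' widths) lands on the tree's target diameter; targets are drawn inside
#' the species diameter range with a mild positive coupling to age.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `trees` (list
#'   of [tree_record()]), `truth` (data frame: `tree_id`, `species`,
#'   `archetype`, `age`, `target_diameter_cm`, `base_width_mm`), and
#'   `true_series` (named list of true width vectors).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  trees <- list(); truth <- list(); true_series <- list()
  idx <- 0L
  for (b in config$species_blocks) {
    if (b$n_trees < 1) next
    for (j in seq_len(b$n_trees)) {
      idx <- idx + 1L
      tree_id <- sprintf("T%02d", idx)
      age <- sample(seq(b$age_range[1], b$age_range[2]), 1L)
      u_age <- if (diff(b$age_range) > 0)
        (age - b$age_range[1]) / diff(b$age_range) else 0.5
      # target diameter: age explains part of the size, the rest is scatter;
      # targets keep a 4%-of-span margin to the range edges so the noisy
      # realized diameters still land inside the configured range
      u <- 0.5 * u_age + 0.5 * stats::runif(1)
      target_d <- b$diameter_range[1] +
        (0.04 + 0.92 * u) * diff(b$diameter_range)
      archetype <- sample(names(b$archetype_weights), 1L,
                          prob = b$archetype_weights)
      # a plateau tree is flat over its whole life: its expected width has
      # no juvenile ramp, otherwise the series genuinely increased and the
      # generative label would be wrong
      ramp <- if (archetype == "plateau") 0L else sample(10:25, 1L)
      params <- archetype_params(
        archetype = archetype,
        juvenile_ramp_years = ramp,
        base_width_mm = 1,     # placeholder, calibrated below
        trend_slope = if (archetype == "plateau") 0
        else stats::runif(1, 0.004, 0.012),
        depression = if (archetype == "increase_with_depression")
          list(start_fraction = stats::runif(1, 0.35, 0.55),
               length_years = sample(25:40, 1L),
               depth_fraction = stats::runif(1, 0.35, 0.5)) else NULL,
        decline = if (archetype == "rise_then_decline")
          list(onset_fraction = 0.5, rate = NA_real_) else NULL,
        ar1_phi = config$ar1_phi,
        noise_cv = config$noise_cv)
      params$base_width_mm <-
        calibrate_base_width(params, age, target_d * 10 / 2)
      tw <- simulate_tree(params, age)
      radii <- realize_radii(tw, radii_per_tree = config$radii_per_tree,
                             radial_noise_cv = config$radial_noise_cv,
                             wedge_ring_prob = config$wedge_ring_prob,
                             tree_id = tree_id, species = b$species,
                             last_year = config$felling_year)
      trees[[tree_id]] <- tree_record(
        tree_id = tree_id, species = b$species, radii = radii,
        wood_density = b$wood_density, stress_E = config$stress_E,
        carbon_fraction = config$carbon_fraction)
      truth[[tree_id]] <- data.frame(
        tree_id = tree_id, species = b$species, archetype = archetype,
        age = age, target_diameter_cm = target_d,
        base_width_mm = params$base_width_mm, stringsAsFactors = FALSE)
      true_series[[tree_id]] <- tw
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else data.frame(tree_id = character(0), species = character(0),
                  archetype = character(0), age = integer(0),
                  target_diameter_cm = numeric(0), base_width_mm = numeric(0),
                  stringsAsFactors = FALSE)
  structure(list(trees = trees, truth = truth_df,
                 true_series = true_series),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d trees, %d species\n",
              length(x$trees), length(unique(x$truth$species))))
  invisible(x)
}
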