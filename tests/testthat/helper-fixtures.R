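# Shared fixture builders; everything is generated in code.

# quick ring_series with defaults
rs <- function(widths, tree_id = "T1", radius_id = "r1", last_year = length(widths),
               species = "C.odorata") {
  ring_series(tree_id, radius_id, widths, last_year = last_year, species = species)
}

# carbon trajectory straight from a width vector
traj_from_widths <- function(widths, rho = 0.6, E = 0, cf = 0.471,
                             tree_id = "T1") {
  m <- rs(widths, tree_id = tree_id)
  carbon_trajectory(reconstruct_diameter(m), rho = rho, E = E,
                    carbon_fraction = cf)
}

# a carbon-like trajectory with prescribed annual accumulation (bypasses
# the allometry so closed-form quartile cases can be asserted exactly)
traj_from_annual <- function(annual, tree_id = "T1") {
  structure(
    data.frame(tree_id = tree_id, year = seq_along(annual),
               age = seq_along(annual), diameter_cm = NA_real_,
               agb_kg = NA_real_, carbon_kg = cumsum(annual),
               annual_c_kg = annual, stringsAsFactors = FALSE),
    class = c("carbon_trajectory", "data.frame"))
}

# brute-force Pettitt statistic: the O(T^2) sign double loop
pettitt_brute <- function(x) {
  n <- length(x)
  U <- vapply(seq_len(n - 1L), function(t) {
    s <- 0
    for (i in seq_len(t)) s <- s + sum(sign(x[i] - x[(t + 1L):n]))
    s
  }, numeric(1))
  list(U_t = U, K = max(abs(U)), tau = which.max(abs(U)))
}

# brute-force Dunn z for two named groups using explicit midranks
dunn_brute_z <- function(groups, a, b) {
  x <- unlist(groups, use.names = FALSE)
  lab <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- vapply(seq_len(N), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))  # midrank by count
  tie_term <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    tie_term <- tie_term + (t^3 - t)
  }
  v0 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  (mean(r[lab == a]) - mean(r[lab == b])) /
    sqrt(v0 * (1 / sum(lab == a) + 1 / sum(lab == b)))
}

# archetype parameter sets as the cohort generator builds them
arch_params <- function(arch, age, noise_cv = 0, ar1_phi = 0, ramp = 15) {
  archetype_params(
    arch,
    juvenile_ramp_years = if (arch == "plateau") 0 else ramp,
    base_width_mm = 1.5,
    trend_slope = if (arch == "plateau") 0 else 0.008,
    noise_cv = noise_cv, ar1_phi = ar1_phi)
}
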