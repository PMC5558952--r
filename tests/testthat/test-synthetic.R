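test_that("noiseless simulation returns the archetype mean structure exactly", {
  ap <- archetype_params("plateau", juvenile_ramp_years = 0,
                         base_width_mm = 1.5, noise_cv = 0)
  expect_equal(simulate_tree(ap, 100), rep(1.5, 100))
  # same seed, same params -> identical series
  ap2 <- archetype_params("sustained_increase", noise_cv = 0.15)
  expect_identical(simulate_tree(ap2, 120, seed = 5),
                   simulate_tree(ap2, 120, seed = 5))
  expect_false(identical(simulate_tree(ap2, 120, seed = 5),
                         simulate_tree(ap2, 120, seed = 6)))
})

test_that("the lognormal noise is mean-corrected and AR(1)-correlated", {
  ap <- archetype_params("plateau", juvenile_ramp_years = 0,
                         base_width_mm = 2, noise_cv = 0.1, ar1_phi = 0.5)
  set.seed(77)
  w <- simulate_tree(ap, 5000)
  expect_equal(mean(w), 2, tolerance = 0.02)
  expect_equal(sd(w) / mean(w), 0.1, tolerance = 0.15)
  expect_equal(stats::acf(log(w), plot = FALSE)$acf[2], 0.5, tolerance = 0.1)
})

test_that("sustained increase without noise has non-decreasing increments and minimal trend p", {
  ap <- archetype_params("sustained_increase", juvenile_ramp_years = 15,
                         base_width_mm = 1.5, trend_slope = 0.008,
                         noise_cv = 0)
  w <- simulate_tree(ap, 100)
  inc <- reconstruct_diameter(rs(w))$increment_cm
  expect_true(all(diff(inc) >= -1e-12))
  r <- cox_stuart(w, alternative = "increasing")
  expect_equal(r$p_value, 0.5^r$n_pairs_used)   # minimal attainable p
  expect_equal(r$n_pairs_used, 50L)
})

test_that("invalid archetype parameters are rejected", {
  expect_error(archetype_params("nonsense"), "arg")
  ap <- archetype_params("rise_then_decline",
                         decline = list(onset_fraction = 0.5, rate = 0.05))
  expect_error(archetype_mean(ap, 200), "non-positive")   # declines through 0
  expect_error(archetype_mean(archetype_params(juvenile_ramp_years = 50), 30),
               "juvenile_ramp_years")
})

test_that("realize_radii reproduces the truth when noise is off", {
  true_w <- round(runif(80, 0.5, 3), 2)
  radii <- realize_radii(true_w, radii_per_tree = 3, radial_noise_cv = 0,
                         wedge_ring_prob = 0, seed = 1)
  for (r in radii) expect_equal(r$widths, true_w)
  expect_error(realize_radii(true_w, radii_per_tree = 1), "radii_per_tree")
  expect_error(realize_radii(true_w, wedge_ring_prob = 1), "wedge_ring_prob")
})

test_that("wedge rings appear at the configured rate but never on every radius", {
  true_w <- rep(2, 400)
  set.seed(23)
  zero_counts <- replicate(30, {
    radii <- realize_radii(true_w, radii_per_tree = 5, radial_noise_cv = 0,
                           wedge_ring_prob = 0.05)
    w <- do.call(rbind, lapply(radii, `[[`, "widths"))
    expect_true(all(colSums(w == 0) < 5))   # never absent everywhere
    sum(w == 0)
  })
  expected <- 5 * 400 * 0.05
  se <- sqrt(30 * 5 * 400 * 0.05 * 0.95)
  expect_lt(abs(sum(zero_counts) - 30 * expected), 4 * se)
})

test_that("averaging radii shrinks the error at the CLT rate", {
  true_w <- rep(2, 300)
  cv <- 0.1; R <- 8
  set.seed(55)
  rel_err <- replicate(40, {
    radii <- realize_radii(true_w, radii_per_tree = R, radial_noise_cv = cv,
                           wedge_ring_prob = 0)
    m <- mean_tree_series(radii)$widths
    sd(m / true_w - 1)
  })
  # per-year relative error of the radius mean ~ cv / sqrt(R)
  expect_equal(mean(rel_err), cv / sqrt(R), tolerance = 0.1)
})

test_that("the default cohort reproduces the study's shape", {
  cohort <- simulate_cohort(default_cohort_config(seed = 101))
  expect_length(cohort$trees, 61L)
  counts <- table(cohort$truth$species)
  expect_equal(as.vector(counts[c("C.odorata", "G.glabra", "H.courbaril")]),
               c(20L, 21L, 20L))
  expect_true(all(cohort$truth$age >= 84 & cohort$truth$age <= 255))
  final_d <- vapply(cohort$trees, function(tr)
    2 * sum(mean_tree_series(tr$radii)$widths) / 10, numeric(1))
  expect_true(all(final_d >= 36.7 & final_d <= 99.2))
  # at least 2 radii per tree, all rounded to the measurement resolution
  for (tr in cohort$trees[1:5]) {
    expect_gte(length(tr$radii), 2L)
    w <- tr$radii[[1]]$widths
    expect_equal(w, round(w / 0.01) * 0.01)
  }
})

test_that("an empty configuration yields an empty cohort", {
  cfg <- default_cohort_config(seed = 1)
  for (i in seq_along(cfg$species_blocks)) cfg$species_blocks[[i]]$n_trees <- 0
  cohort <- simulate_cohort(cfg)
  expect_length(cohort$trees, 0L)
  expect_equal(nrow(cohort$truth), 0L)
})

test_that("a fixed seed gives a byte-identical RWL export", {
  cfg <- default_cohort_config(seed = 77)
  cfg$species_blocks <- cfg$species_blocks[1]
  cfg$species_blocks[[1]]$n_trees <- 4
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  for (f in c(f1, f2)) {
    cohort <- simulate_cohort(cfg)
    write_rwl(unlist(lapply(cohort$trees, `[[`, "radii"), recursive = FALSE), f)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("base-width calibration hits the target diameter on the mean structure", {
  for (arch in growth_archetypes()) {
    p <- arch_params(arch, 150)
    p$base_width_mm <- ringcarbon:::calibrate_base_width(p, 150, 250)
    expect_equal(sum(archetype_mean(p, 150)), 250, tolerance = 1e-4)
  }
  expect_error(ringcarbon:::calibrate_base_width(arch_params("plateau", 100),
                                                 100, 1e6), "unreachable")
})
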