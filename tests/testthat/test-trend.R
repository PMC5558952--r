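test_that("Cox-Stuart p-values are exact binomial tails", {
  r <- cox_stuart(1:20, alternative = "increasing")
  expect_equal(r$n_pairs_used, 10L)
  expect_equal(r$s_plus, 10L)
  expect_equal(r$p_value, 0.5^10)
  expect_equal(r$direction, "increasing")
  # two-sided doubles the smaller tail
  expect_equal(cox_stuart(1:20)$p_value, 2 * 0.5^10)
  expect_equal(cox_stuart(20:1)$direction, "decreasing")
  # odd length drops the middle element
  expect_equal(cox_stuart(1:21)$n_pairs_used, 10L)
  # constant series is degenerate
  d <- cox_stuart(rep(1, 12))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  expect_equal(d$direction, "none")
  expect_error(cox_stuart(1:3), "length >= 4")
})

test_that("Cox-Stuart and Pettitt are invariant under monotone transforms", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(60)
    f <- function(z) exp(z) + z^3      # strictly increasing
    a <- cox_stuart(x); b <- cox_stuart(f(x))
    expect_equal(a$s_plus, b$s_plus)
    expect_equal(a$p_value, b$p_value)
    pa <- pettitt(x); pb <- pettitt(f(x))
    expect_equal(pa$K, pb$K)
    expect_equal(pa$tau, pb$tau)
  }
})

test_that("Cox-Stuart empirical size sits in the binomial envelope of its attainable size", {
  n <- 100; reps <- 2000; alpha <- 0.05
  m <- n %/% 2
  # attainable size of the discrete two-sided test with m untied pairs
  k <- 0:m
  p2 <- pmin(1, 2 * pmin(pbinom(k, m, 0.5), pbinom(k - 1, m, 0.5, lower.tail = FALSE)))
  size_att <- sum(dbinom(k, m, 0.5)[p2 <= alpha])
  set.seed(2024)
  rejects <- sum(replicate(reps, cox_stuart(rnorm(n))$p_value <= alpha))
  env <- qbinom(c(0.005, 0.995), reps, size_att)
  expect_gte(rejects, env[1])
  expect_lte(rejects, env[2])
})

test_that("Pettitt matches the sign double-sum on the hand-checkable step", {
  p <- pettitt(c(rep(0, 50), rep(10, 50)))
  expect_equal(p$K, 2500)
  expect_equal(p$tau, 50L)
  expect_lt(p$p_approx, 1e-10)
  # constant series: no shift, capped p
  pc <- pettitt(rep(2, 30))
  expect_equal(pc$K, 0)
  expect_equal(pc$p_approx, 1)
  expect_error(pettitt(1:5), "length >= 8")
})

test_that("Pettitt equals the O(T^2) brute force on a random battery", {
  set.seed(99)
  for (i in 1:200) {
    T <- sample(8:30, 1)
    x <- if (i %% 3 == 0) sample(1:5, T, replace = TRUE)  # heavy ties
    else rnorm(T)
    got <- pettitt(x)
    want <- pettitt_brute(x)
    expect_equal(got$U_t, want$U_t)
    expect_equal(got$K, want$K)
    expect_equal(got$tau, want$tau)
  }
})

test_that("Dunn z matches the rank formula on the untied hand case", {
  d <- dunn_test(list(a = 1:3, b = 10:12))
  expect_equal(d$z, -3 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(d$p_raw, 2 * pnorm(-abs(d$z)))
  # identical groups: z = 0, p = 1
  d0 <- dunn_test(list(a = c(1, 5, 9), b = c(1, 5, 9)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_raw, 1)
  expect_error(dunn_test(list(a = c(2, 2), b = c(2, 2))), "degenerate")
})

test_that("tie-corrected Dunn z matches an independent midrank brute force", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:6, sample(3:8, 1), replace = TRUE))  # plenty of ties
    names(groups) <- paste0("g", seq_len(k))
    if (length(unique(unlist(groups))) == 1L) next
    got <- dunn_test(groups, adjustment = "holm")
    for (r in seq_len(nrow(got))) {
      zb <- dunn_brute_z(groups, got$group_a[r], got$group_b[r])
      expect_equal(got$z[r], zb, tolerance = 1e-12)
    }
    expect_true(all(got$p_adjusted >= got$p_raw))
    # Holm keeps the ordering of raw p-values
    expect_true(all(diff(got$p_adjusted[order(got$p_raw)]) >= -1e-15))
  }
})

test_that("pearson_correlation recovers exact correlations and contracts", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r1 <- pearson_correlation(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(4)
  y <- rnorm(30); z <- 0.5 * y + rnorm(30)
  r2 <- pearson_correlation(y, z)
  tt <- r2$r * sqrt((30 - 2) / (1 - r2$r^2))
  expect_equal(r2$p_value, 2 * pt(-abs(tt), 28))
  expect_error(pearson_correlation(y, rep(1, 30)), "zero variance")
})

test_that("compare_species runs ANOVA plus Holm-adjusted pooled-SD t-tests", {
  x <- c(1, 2, 3, 4)
  same <- compare_species(rep(x, 3), rep(c("a", "b", "c"), each = 4))
  expect_lt(same$anova$F, 1e-20)
  expect_equal(same$pairwise$p_adjusted, rep(1, 3))
  # two groups: Holm = raw p (single comparison)
  set.seed(6)
  v <- c(rnorm(10), rnorm(10, 1))
  g <- rep(c("a", "b"), each = 10)
  two <- compare_species(v, g)
  raw <- pairwise.t.test(v, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(two$pairwise$p_adjusted, as.vector(raw$p.value))
  expect_warning(compare_species(c(v, 5), c(g, "tiny")), "excluding")
})

test_that("compare_species separates a shifted group with high power", {
  set.seed(31)
  hits_shift <- 0; false_null <- 0; reps <- 500
  for (i in seq_len(reps)) {
    v <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 5))
    g <- rep(c("a", "b", "c"), each = 20)
    pw <- compare_species(v, g)$pairwise
    vs_c <- pw$p_adjusted[pw$group_a == "c" | pw$group_b == "c"]
    ab <- pw$p_adjusted[(pw$group_a %in% c("a", "b")) &
                          (pw$group_b %in% c("a", "b"))]
    if (all(vs_c <= 0.05)) hits_shift <- hits_shift + 1
    if (ab <= 0.05) false_null <- false_null + 1
  }
  expect_gte(hits_shift / reps, 0.95)
  expect_lte(false_null / reps, 0.10)
})
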