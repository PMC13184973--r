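# brute-force SAR oracle: average richness over all n-subsets of samples
enum_sar <- function(pa, n) {
  subsets <- utils::combn(ncol(pa), n)
  mean(apply(subsets, 2, function(s)
    sum(rowSums(pa[, s, drop = FALSE]) > 0)))
}

test_that("sar_exact matches the hand case and exhaustive enumeration for N <= 6", {
  pa <- rbind(A = c(TRUE, TRUE, TRUE), B = c(TRUE, FALSE, FALSE))
  colnames(pa) <- sprintf("s%d", 1:3)
  curve <- sar_exact(pa)
  expect_equal(curve$expected_richness, c(4 / 3, 5 / 3, 2))
  expect_equal(curve$expected_richness[3], 2)  # n = N gives total richness
  set.seed(14)
  for (N in 3:6) {
    m <- matrix(stats::runif(10 * N) < 0.4, 10, N,
                dimnames = list(sprintf("t%02d", 1:10), sprintf("s%d", 1:N)))
    if (all(rowSums(m) == 0)) next
    curve <- sar_exact(m)
    for (n in 1:N) {
      expect_equal(curve$expected_richness[n], enum_sar(m, n),
                   tolerance = 1e-10, label = sprintf("N=%d n=%d", N, n))
    }
  }
})

test_that("sar_exact agrees with vegan's exact species accumulation", {
  sim <- small_sim()
  pa <- presence_absence(sim$counts)
  pa <- pa[rowSums(pa) > 0, ]
  ours <- sar_exact(pa)
  veg <- suppressWarnings(vegan::specaccum(t(pa) * 1, method = "exact"))
  expect_equal(ours$expected_richness, unname(veg$richness), tolerance = 1e-8)
})

test_that("randomised SAR converges to the exact curve and is seeded", {
  sim <- small_sim()
  pa <- presence_absence(sim$counts)
  exact <- sar_exact(pa)
  rand <- sar_random(pa, n_perm = 200, seed = 3)
  se <- rand$richness_sd / sqrt(200)
  mid <- 2:(nrow(rand) - 1)        # endpoints are deterministic
  expect_true(all(abs(rand$expected_richness[mid] -
                        exact$expected_richness[mid]) <= 4 * se[mid] + 0.5))
  expect_identical(sar_random(pa, n_perm = 5, seed = 9),
                   sar_random(pa, n_perm = 5, seed = 9))
  expect_true(all(diff(rand$expected_richness) >= 0))
  one <- sar_random(pa[, 1, drop = FALSE], n_perm = 3, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$expected_richness, sum(pa[, 1]))
})

test_that("unequal sample areas shift the area coordinate correctly", {
  pa <- matrix(TRUE, 2, 4, dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  areas <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(sar_exact(pa, areas)$area, cumsum(rep(mean(areas), 4)))
  rand <- sar_random(pa, areas, n_perm = 50, seed = 2)
  expect_equal(rand$area[4], 1)    # full coverage regardless of ordering
})

test_that("noiseless scaling-law fixtures are recovered to numerical precision", {
  a <- seq(0.05, 1, by = 0.05)
  fpl <- fit_scaling_law(data.frame(area = a, expected_richness = 10 * a^0.25),
                         "PL")
  expect_true(fpl$converged)
  expect_equal(fpl$c, 10, tolerance = 1e-6)
  expect_equal(fpl$z, 0.25, tolerance = 1e-6)
  expect_lt(fpl$rmse, 1e-8)
  # LPL with b = 0, z = 1 degenerates to c * log(A); keep areas > 1 so the
  # law stays positive
  a2 <- seq(2, 20)
  flpl <- fit_scaling_law(data.frame(area = a2,
                                     expected_richness = 3 * log(a2)), "LPL")
  expect_true(flpl$converged)
  expect_lt(flpl$rmse, 1e-6)
  expect_equal(predict(flpl, a2), 3 * log(a2), tolerance = 1e-4)
  # generating law always beats the other on its own noiseless fixture
  lpl_pts <- data.frame(area = seq(0.3, 1, by = 0.05))
  lpl_pts$expected_richness <- (2 + 3 * log(lpl_pts$area) + 4)^1.5
  expect_lt(fit_scaling_law(lpl_pts, "LPL")$rmse,
            fit_scaling_law(lpl_pts, "PL")$rmse)
  pl_pts <- data.frame(area = a, expected_richness = 10 * a^0.25)
  expect_lt(fit_scaling_law(pl_pts, "PL")$rmse,
            fit_scaling_law(pl_pts, "LPL")$rmse)
})

test_that("power-law turnover exponents are recovered under 5% noise", {
  set.seed(99)
  a <- seq(0.02, 1, length.out = 30)
  for (z in c(0.1, 0.25, 0.5)) {
    hits <- replicate(50, {
      R <- 10 * a^z * exp(stats::rnorm(length(a), 0, 0.05))
      f <- fit_scaling_law(data.frame(area = a, expected_richness = R), "PL")
      abs(f$z - z) <= 0.05
    })
    expect_gte(mean(hits), 0.9)
  }
})

test_that("predict() reproduces the fitted laws", {
  a <- seq(0.1, 1, by = 0.1)
  fpl <- fit_scaling_law(data.frame(area = a, expected_richness = 8 * a^0.3),
                         "PL")
  expect_equal(predict(fpl, a), 8 * a^0.3, tolerance = 1e-5)
})

test_that("compare_laws is deterministic and pairs both fits per curve", {
  sim <- small_sim()
  c1 <- compare_laws(sim$counts, sim$metadata, n_sar = 5, seed = 4)
  c2 <- compare_laws(sim$counts, sim$metadata, n_sar = 5, seed = 4)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$results), 5)
  expect_true(all(c1$results$rmse_pl >= 0))
  expect_lte(c1$win_fraction_pl + c1$win_fraction_lpl, 1)
})

test_that("turnover sweep records both laws for every condition", {
  sim <- small_sim()
  tv <- turnover_vs_samplesize(sim$counts, sim$metadata, k_values = c(1, 2),
                               strategies = "contiguous", depth = 2000,
                               iterations = 2, seed = 6,
                               n_perm_per_curve = 5)
  expect_setequal(unique(tv$law), c("PL", "LPL"))
  expect_equal(nrow(tv), 2 * 2 * 2)
  expect_identical(tv, turnover_vs_samplesize(sim$counts, sim$metadata,
                                              k_values = c(1, 2),
                                              strategies = "contiguous",
                                              depth = 2000, iterations = 2,
                                              seed = 6, n_perm_per_curve = 5))
})

test_that("a perfect power law extrapolates total richness from the smallest prefix", {
  a <- seq(0.04, 1, by = 0.04)
  curve <- data.frame(area = a, expected_richness = 100 * a^0.3)
  r <- area_for_richness_error(curve, "PL", tolerance = 0.1)
  expect_true(r$reached)
  expect_equal(r$n_points_used, 3L)
  inf <- area_for_richness_error(curve, "PL", tolerance = Inf)
  expect_equal(inf$n_points_used, 3L)
})
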