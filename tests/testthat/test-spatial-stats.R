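# independent oracles built on stats::cor and arrangement enumeration

# exact two-sided Spearman p by brute-force permutation of y against x
enum_spearman_p <- function(x, y) {
  obs <- abs(stats::cor(x, y, method = "spearman"))
  perms <- NULL
  permute <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], permute(v[-i]))))
  }
  all_y <- permute(y)
  rhos <- apply(all_y, 1, function(yy) stats::cor(x, yy, method = "spearman"))
  mean(abs(rhos) >= obs - 1e-12)
}

# exact lower/upper runs-tail by enumerating all arrangements of n1 + n2 symbols
enum_runs_tails <- function(n1, n2, r_obs) {
  pos <- utils::combn(n1 + n2, n1)
  runs <- apply(pos, 2, function(p) {
    s <- rep(FALSE, n1 + n2); s[p] <- TRUE
    1 + sum(s[-1] != s[-length(s)])
  })
  c(lower = mean(runs <= r_obs), upper = mean(runs >= r_obs))
}

test_that("Spearman trend matches signs, hand cases and the permutation oracle", {
  expect_equal(spearman_trend(1:6, 1:6)$rho, 1)
  expect_equal(spearman_trend(6:1, 1:6)$rho, -1)
  st <- spearman_trend(c(1, 2, 3, 5, 4), 1:5)
  expect_equal(st$rho, 0.9)
  expect_equal(st$p, 10 / 120)   # 2*(1 + 4) of 120 permutations reach |rho|>=0.9
  # oracle agreement for n <= 7, with and without ties
  set.seed(21)
  for (n in 4:7) for (i in 1:3) {
    x <- seq_len(n)
    y <- sample(c(stats::rnorm(n - 1), 0))
    if (i == 3) y[2] <- y[1]   # force a tie
    st <- spearman_trend(y, x)
    expect_equal(st$p, enum_spearman_p(x, y), tolerance = 1e-12,
                 label = sprintf("n=%d rep=%d", n, i))
  }
  # degenerate constant series
  d <- spearman_trend(rep(2, 5), 1:5)
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  expect_error(spearman_trend(1:3, 1:3), ">= 4")
})

test_that("t-approximation p-values are sane for longer series", {
  set.seed(5)
  x <- 1:30
  y <- x + stats::rnorm(30, 0, 2)
  st <- spearman_trend(y, x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(st$rho, unname(ct$estimate))
  expect_lt(st$p, 1e-6)
})

test_that("runs test matches hand case and the arrangement-enumeration oracle", {
  rt <- runs_test(c(1, 1, 1, 0, 0, 0))
  expect_equal(rt$runs, 2L)
  expect_equal(rt$n1, 3L)
  expect_equal(rt$n2, 3L)
  expect_equal(rt$p, 2 * (2 / 20))   # one tail 0.1, doubled
  # alternating series has the maximal number of runs and a small p
  alt <- runs_test(rep(c(1, 5), 6))
  expect_equal(alt$runs, 12L)
  expect_lt(alt$p, 0.01)
  # oracle agreement over assorted (n1, n2, r)
  for (nn in list(c(3, 3), c(4, 2), c(5, 5), c(6, 4))) {
    dist <- biofilmgeo:::runs_distribution(nn[1], nn[2])
    for (r in dist$runs) {
      tails <- enum_runs_tails(nn[1], nn[2], r)
      expect_equal(sum(dist$prob[dist$runs <= r]), unname(tails["lower"]),
                   tolerance = 1e-12)
      expect_equal(sum(dist$prob[dist$runs >= r]), unname(tails["upper"]),
                   tolerance = 1e-12)
    }
  }
  expect_error(runs_test(rep(3, 8)), "degenerate")
})

test_that("exact runs distribution is a probability distribution up to n1 = n2 = 12", {
  for (n1 in 1:12) for (n2 in 1:12) {
    expect_equal(sum(biofilmgeo:::runs_distribution(n1, n2)$prob), 1,
                 tolerance = 1e-10, label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("exact and normal-approximation runs p-values agree at moderate n", {
  # compare the two regimes on the same (n1 = n2 = 10) configurations
  dist <- biofilmgeo:::runs_distribution(10, 10)
  mu <- 2 * 100 / 20 + 1
  sigma <- sqrt(2 * 100 * (2 * 100 - 20) / (20^2 * 19))
  for (r in dist$runs) {
    exact <- min(1, 2 * min(sum(dist$prob[dist$runs <= r]),
                            sum(dist$prob[dist$runs >= r])))
    approx <- min(1, 2 * min(stats::pnorm((r - mu + 0.5) / sigma),
                             stats::pnorm((r - mu - 0.5) / sigma,
                                          lower.tail = FALSE)))
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("BH adjustment in trend classification is monotone and conservative", {
  sim <- small_sim()
  tr <- classify_trends(sim$counts, sim$metadata)
  expect_true(all(tr$rho_p_adj >= tr$spearman_p - 1e-12))
  expect_true(all(tr$runs_p_adj >= tr$runs_p - 1e-12))
  ord <- order(tr$spearman_p)
  expect_true(all(diff(tr$rho_p_adj[ord]) >= -1e-12))
  expect_lte(sum(tr$rho_p_adj <= 0.05), sum(tr$spearman_p <= 0.05))
  # deterministic given the table
  expect_identical(tr, classify_trends(sim$counts, sim$metadata))
})

test_that("an unstructured community yields almost no trend calls (FDR control)", {
  frac <- vapply(1:5, function(s) {
    sim <- generate_biofilm(synthetic_config(
      n_taxa = 150, n_sections = 80, n_sides = 1, depth = 5000,
      frac_monotonic = 0, frac_peaked = 0, noise_overdispersion = 20,
      seed = s))
    tr <- classify_trends(sim$counts, sim$metadata)
    mean(tr$classification != "none")
  }, numeric(1))
  expect_true(all(frac <= 0.05))
})

test_that("noiseless two-segment data are fit exactly and nest the single line", {
  dd <- generate_distance_decay(n = 200, breakpoint_cm = 30, slope1 = 0.01,
                                slope2 = 0.002, intercept = 0.2, noise_sd = 0,
                                seed = 1)
  bp <- breakpoint_fit(dd$distance_cm, dd$dissimilarity, n_boot = 0)
  expect_equal(bp$breakpoint_cm, 30, tolerance = 0.5)
  expect_lt(bp$sse, 1e-8)
  expect_equal(bp$slope_left, 0.01, tolerance = 1e-3)
  expect_equal(bp$slope_right, 0.002, tolerance = 1e-3)
  expect_true(bp$supported)
  # the two-segment SSE never exceeds the single-line SSE
  set.seed(3)
  for (i in 1:5) {
    x <- stats::runif(60, 0, 100)
    y <- stats::runif(60)
    f <- breakpoint_fit(x, y, n_boot = 0)
    expect_lte(f$sse, f$sse_single_line + 1e-10)
  }
})

test_that("single-slope data are flagged as having no supported breakpoint", {
  dd <- generate_distance_decay(n = 200, breakpoint_cm = 30, slope1 = 0.005,
                                slope2 = 0.005, noise_sd = 0.01, seed = 4)
  bp <- breakpoint_fit(dd$distance_cm, dd$dissimilarity, n_boot = 0)
  expect_false(bp$supported)
})

test_that("breakpoint and its bootstrap error recover the simulated truth", {
  hits <- vapply(1:10, function(s) {
    dd <- generate_distance_decay(n = 500, breakpoint_cm = 40, slope1 = 0.012,
                                  slope2 = 0.002, intercept = 0.2,
                                  noise_sd = 0.02, seed = s)
    bp <- breakpoint_fit(dd$distance_cm, dd$dissimilarity, n_boot = 40,
                         seed = s + 100)
    abs(bp$breakpoint_cm - 40) <= 3 * bp$breakpoint_se_cm
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
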