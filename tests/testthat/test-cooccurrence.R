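# independent oracle: enumerate every placement of taxon B's presences
# against a fixed placement of taxon A and count overlaps >= X
enum_pair_p <- function(X, mA, mB, N) {
  a <- seq_len(mA)
  placements <- utils::combn(N, mB)
  mean(apply(placements, 2, function(b) sum(b %in% a)) >= X)
}

test_that("presence_absence thresholds counts and is idempotent", {
  m <- matrix(c(0L, 3L, 1L, 5L), 2, 2, dimnames = list(c("a", "b"),
                                                       c("s1", "s2")))
  pa <- presence_absence(m)
  expect_identical(unname(pa[, 1]), c(FALSE, TRUE))
  expect_true(all(presence_absence(m, min_count = 6) == FALSE))
  expect_identical(presence_absence(pa * 1L), pa)
  expect_error(presence_absence(m, 0), "min_count")
})

test_that("pair_pvalue matches small-case enumeration and the full N <= 8 oracle", {
  expect_equal(pair_pvalue(2, 2, 2, 4), 1 / 6)
  # minimal possible overlap spans the whole support
  expect_equal(pair_pvalue(max(0, 3 + 6 - 8), 3, 6, 8), 1)
  for (N in c(5, 8)) {
    for (mA in 1:(N - 1)) for (mB in 1:(N - 1)) {
      lo <- max(0, mA + mB - N); hi <- min(mA, mB)
      for (X in lo:hi) {
        expect_equal(pair_pvalue(X, mA, mB, N), enum_pair_p(X, mA, mB, N),
                     tolerance = 1e-12,
                     label = sprintf("N=%d mA=%d mB=%d X=%d", N, mA, mB, X))
      }
    }
  }
  expect_error(pair_pvalue(5, 2, 2, 8), "infeasible")
})

test_that("pair_pvalue is symmetric in marginals and monotone in X", {
  for (N in c(6, 10)) {
    set.seed(N)
    for (i in 1:10) {
      mA <- sample(N - 1, 1); mB <- sample(N - 1, 1)
      lo <- max(0, mA + mB - N); hi <- min(mA, mB)
      X <- sample(lo:hi, 1)
      expect_equal(pair_pvalue(X, mA, mB, N), pair_pvalue(X, mB, mA, N))
      if (hi > lo) {
        ps <- vapply(lo:hi, pair_pvalue, numeric(1), mA = mA, mB = mB, N = N)
        expect_true(all(diff(ps) <= 1e-12))
      }
    }
  }
})

test_that("ubiquitous taxa are excluded from pair testing and counted apart", {
  pa <- rbind(ubiq = rep(TRUE, 6),
              gone = rep(FALSE, 6),
              a = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
              b = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  colnames(pa) <- sprintf("s%d", 1:6)
  cs <- count_significant(pa, alpha_level = 0.05, bh = FALSE)
  expect_equal(cs$n_ubiquitous, 1L)
  expect_equal(cs$n_dropped, 1L)
  expect_equal(cs$n_taxa_tested, 2L)
  expect_false(any(c("ubiq", "gone") %in%
                     c(cs$pair_records$taxon_a, cs$pair_records$taxon_b)))
  # a/b share a pattern over 3 of 6 samples: p = 1/C(6,3) = 0.05
  expect_equal(cs$pair_records$p, 1 / 20)
  expect_equal(cs$n_significant_pairs, 1L)
})

test_that("identical presence over 10 of 20 samples is maximally significant", {
  pa <- rbind(a = c(rep(TRUE, 10), rep(FALSE, 10)),
              b = c(rep(TRUE, 10), rep(FALSE, 10)),
              filler = c(rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 5)))
  colnames(pa) <- sprintf("s%02d", 1:20)
  cs <- count_significant(pa, alpha_level = 0.05, bh = TRUE)
  rec <- cs$pair_records
  p_ab <- rec$p[rec$taxon_a == "a" & rec$taxon_b == "b"]
  expect_equal(p_ab, 1 / choose(20, 10))
  expect_true(rec$significant[rec$taxon_a == "a" & rec$taxon_b == "b"])
})

test_that("independent random presence yields no significant pairs under BH", {
  clean <- vapply(1:10, function(s) {
    set.seed(s)
    pa <- matrix(stats::runif(50 * 100) < 0.5, 50, 100,
                 dimnames = list(sprintf("t%02d", 1:50),
                                 sprintf("s%03d", 1:100)))
    count_significant(pa, alpha_level = 0.05, bh = TRUE)$n_significant_pairs == 0L
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("pooling segregated patches converts checkerboards into co-occurrences", {
  # 10 blocks of 4 sections; odd blocks are populated patches in which taxa
  # a and b segregate (a in the first 2 sections, b in the last 2), even
  # blocks are barren
  populated <- rep(rep(c(TRUE, FALSE), each = 4), 5)
  a <- populated & rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  b <- populated & rep(c(FALSE, FALSE, TRUE, TRUE), 10)
  pa <- rbind(a = a, b = b)
  colnames(pa) <- sprintf("s%02d", 1:40)
  before <- count_significant(pa, alpha_level = 0.05, bh = FALSE)
  expect_equal(before$pair_records$X, 0L)      # perfectly segregated
  expect_equal(before$n_significant_pairs, 0L)
  # pool at the block scale: both taxa co-occur in exactly the populated pools
  pooled <- sapply(seq(1, 40, by = 4), function(j) rowSums(pa[, j:(j + 3)]) > 0)
  colnames(pooled) <- sprintf("p%02d", 1:10)
  after <- count_significant(pooled, alpha_level = 0.05, bh = FALSE)
  expect_equal(after$pair_records$p, 1 / choose(10, 5))
  expect_gt(after$n_significant_pairs, before$n_significant_pairs)
})

test_that("equalized sweep is deterministic and collapses to count_significant", {
  sim <- small_sim()
  plan <- sampling_plan("contiguous", k = 2, rarefaction_depth = 2000,
                        iterations = 1, seed = 5)
  sets <- list(cond = apply_plan(sim$counts, sim$metadata, plan))
  n_all <- ncol(sets$cond[[1]]$counts)
  sw1 <- equalized_sweep(sets, n_select = n_all, iterations = 3, seed = 9)
  sw2 <- equalized_sweep(sets, n_select = n_all, iterations = 3, seed = 9)
  expect_identical(sw1, sw2)
  direct <- count_significant(presence_absence(sets$cond[[1]]$counts))
  expect_true(all(sw1$n_significant_pairs == direct$n_significant_pairs))
  expect_true(all(sw1$n_ubiquitous == direct$n_ubiquitous))
  expect_error(equalized_sweep(sets, n_select = n_all + 1), "exceeds")
})
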