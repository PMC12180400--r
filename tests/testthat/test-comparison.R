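ft <- function(species, fo, method = "PC", site = "S") {
  out <- data.frame(species = species, fo = fo, stringsAsFactors = FALSE)
  attr(out, "n_units") <- 100
  attr(out, "method") <- method
  attr(out, "site") <- site
  class(out) <- c("frequency_table", "data.frame")
  out
}

test_that("pairing spans the union universe with zero fill", {
  x <- ft(c("a", "b"), c(0.4, 0.2))
  y <- ft(c("b", "c"), c(0.1, 0.3), method = "ARU")
  p <- pair_frequencies(x, y)
  expect_equal(p$species, c("a", "b", "c"))  # lexicographic
  expect_equal(p$fo_x, c(0.4, 0.2, 0))
  expect_equal(p$fo_y, c(0, 0.1, 0.3))
  expect_equal(p$diff, p$fo_x - p$fo_y)

  same <- pair_frequencies(x, x)
  expect_true(all(same$diff == 0))

  set.seed(5)
  sx <- sample(letters, 12); sy <- sample(letters, 9)
  p2 <- pair_frequencies(ft(sx, runif(12)), ft(sy, runif(9)))
  expect_equal(nrow(p2), length(union(sx, sy)))
  expect_error(pair_frequencies(x, ft("a", 1, site = "T")),
               "different sites")
})

test_that("KS statistic matches the sup-deviation oracle", {
  expect_identical(ks_normality(0)$ks_stat, 0.5)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(c(1, 2, 5, 20, 80), 1)
    x <- switch(1 + i %% 3,
                rnorm(n), runif(n, -1, 1), round(rnorm(n), 1))  # incl. ties
    got <- ks_normality(x)$ks_stat
    expect_equal(got, oracle_ks_stat(x), tolerance = 1e-9)
    # independent cross-check against the reference implementation
    if (!any(duplicated(x))) {
      expect_equal(got,
                   unname(suppressWarnings(
                     stats::ks.test(x, "pnorm")$statistic)),
                   tolerance = 1e-12)
    }
  }
})

test_that("KS p-value is asymptotically calibrated under the null", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    ks_normality(rnorm(10000))$ks_p > 0.05
  }, logical(1))
  expect_gte(sum(ok), 18)  # >= 90% of seeds
  # far-from-normal data are strongly rejected
  expect_lt(ks_normality(runif(200, 10, 11))$ks_p, 1e-10)
})

test_that("signed-rank test matches exhaustive enumeration", {
  w <- wilcoxon_signed_rank(1:6)
  expect_equal(w$w_minus, 0)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 64)
  expect_true(w$exact)

  set.seed(12)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), 6)
    d <- d[d != 0]
    if (length(d) < 3 || any(duplicated(abs(d)))) next
    got <- wilcoxon_signed_rank(d)
    orc <- oracle_wilcoxon_exact(d)
    expect_equal(got$statistic, orc$statistic)
    expect_equal(got$p_value, orc$p_value)
    # reference implementation agrees on tie-free data
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(got$w_plus + got$w_minus,
                 length(d) * (length(d) + 1) / 2)
  }
})

test_that("signed-rank test is symmetric and handles zeros and ties", {
  d <- c(0.3, -0.1, 0.8, -0.5, 0.2, 0.9, -0.4)
  a <- wilcoxon_signed_rank(d)
  b <- wilcoxon_signed_rank(-d)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$w_plus, b$w_minus)

  # zeros dropped
  z <- wilcoxon_signed_rank(c(d, 0, 0))
  expect_equal(z$n_used, length(d))
  expect_equal(z$p_value, a$p_value)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")

  # tied absolute values get mid-ranks; enumeration still exact
  dt <- c(0.5, -0.5, 0.5, 1, -2)
  got <- wilcoxon_signed_rank(dt)
  orc <- oracle_wilcoxon_exact(dt)
  expect_equal(got$p_value, orc$p_value)
})

test_that("normal approximation is close to exact at n = 12", {
  set.seed(33)
  for (i in 1:10) {
    d <- rnorm(12)
    ex <- wilcoxon_signed_rank(d, exact_limit = 12)
    ap <- wilcoxon_signed_rank(d, exact_limit = 0)
    expect_true(ex$exact); expect_false(ap$exact)
    expect_lt(abs(ex$p_value - ap$p_value), 0.02)
  }
})

test_that("paired t matches the textbook formula and guards degeneracy", {
  set.seed(14)
  d <- rnorm(20, 0.2)
  tt <- paired_t(d)
  expect_equal(tt$statistic, mean(d) / (sd(d) / sqrt(20)))
  ref <- stats::t.test(d)
  expect_equal(tt$p_value, unname(ref$p.value))
  expect_equal(paired_t(c(1, -1, 1, -1))$statistic, 0)
  expect_equal(paired_t(c(1, -1, 1, -1))$p_value, 1)
  cst <- paired_t(rep(2, 5))
  expect_true(cst$degenerate)
  expect_identical(cst$statistic, Inf)
  expect_equal(cst$p_value, 0)
})

test_that("the normality gate selects the right test", {
  # spike at zero plus outliers: grossly non-normal differences
  x <- ft(paste0("s", 1:60), c(rep(0.02, 50), rep(0.9, 10)))
  y <- ft(paste0("s", 1:60), c(rep(0.02, 50), rep(0.1, 10)), method = "ARU")
  cmp <- compare_methods(x, y)
  expect_equal(cmp$test_used, "wilcoxon")
  expect_lt(cmp$ks_p, 0.05)
  expect_equal(cmp$n_pairs, 10)

  # identical tables: inconclusive, not an error
  same <- compare_methods(x, x)
  expect_equal(same$test_used, "inconclusive")
  expect_true(is.na(same$p_value))

  # near-standard-normal differences pass the gate to the paired t
  set.seed(3)
  d <- rnorm(80)
  xn <- ft(paste0("s", 1:80), d)        # fo columns are synthetic here;
  yn <- ft(paste0("s", 1:80), rep(0, 80), method = "ARU")
  cmp_n <- compare_methods(xn, yn)
  expect_equal(cmp_n$test_used, "paired_t")
})

test_that("comparison is symmetric under method swap", {
  set.seed(6)
  x <- ft(paste0("s", 1:40), runif(40))
  y <- ft(paste0("s", 1:40), runif(40), method = "ARU")
  ab <- compare_methods(x, y)
  ba <- compare_methods(y, x)
  expect_equal(ab$p_value, ba$p_value)
  if (ab$test_used == "paired_t") {
    expect_equal(ab$statistic, -ba$statistic)
  } else {
    expect_equal(ab$statistic, ba$statistic)
  }
})

test_that("p-value decreases with the size of a true FO shift", {
  median_p <- vapply(c(0, 0.15, 0.35), function(shift) {
    ps <- vapply(1:9, function(s) {
      set.seed(100 + s)
      base <- runif(50, 0.05, 0.6)
      x <- ft(paste0("s", 1:50), pmin(1, base + shift))
      y <- ft(paste0("s", 1:50),
              pmin(1, base + rnorm(50, 0, 0.05)), method = "ARU")
      compare_methods(x, y)$p_value
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(median_p) <= 0))
  expect_lt(median_p[3], 1e-4)
})

test_that("matched-effort null comparisons reject at about alpha", {
  # both methods driven by identical per-species detection probabilities
  # over the same number of units: the gate + test should be calibrated
  set.seed(77)
  n_rep <- 200
  rej <- vapply(seq_len(n_rep), function(i) {
    p <- runif(45, 0.1, 0.9)
    fo_a <- rbinom(45, 40, p) / 40
    fo_b <- rbinom(45, 40, p) / 40
    keep <- fo_a > 0 | fo_b > 0
    x <- ft(paste0("s", 1:45)[keep], fo_a[keep])
    y <- ft(paste0("s", 1:45)[keep], fo_b[keep], method = "ARU")
    cmp <- suppressWarnings(compare_methods(x, y))
    isTRUE(cmp$p_value < 0.05)
  }, logical(1))
  rate <- mean(rej)
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.12)
})
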