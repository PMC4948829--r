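test_that("divergence_fraction counts and bounds behave", {
  est0 <- divergence_fraction(rep(FALSE, 50))
  expect_equal(est0$fraction, 0)
  expect_equal(est0$ci_low, 0)
  est1 <- divergence_fraction(rep(TRUE, 50))
  expect_equal(est1$fraction, 1)
  expect_equal(est1$ci_high, 1)
  est <- divergence_fraction(c(rep(TRUE, 3), rep(FALSE, 32)))
  expect_equal(est$fraction, 3 / 35, tolerance = 1e-12)
  expect_error(divergence_fraction(logical(0)), "no calls")
})

test_that("Clopper-Pearson interval matches the beta quantile form", {
  for (k in c(0, 3, 17, 35)) {
    n <- 35
    est <- divergence_fraction(c(rep(TRUE, k), rep(FALSE, n - k)))
    lo <- if (k == 0) 0 else qbeta(0.025, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(0.975, k + 1, n - k)
    expect_equal(est$ci_low, lo, tolerance = 1e-9)
    expect_equal(est$ci_high, hi, tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(71)
  for (f in c(0.01, 0.086, 0.3)) {
    n <- 35
    ks <- rbinom(4000, n, f)
    lo <- ifelse(ks == 0, 0, qbeta(0.025, ks, n - ks + 1))
    hi <- ifelse(ks == n, 1, qbeta(0.975, ks + 1, n - ks))
    expect_gte(mean(lo <= f & f <= hi), 0.95)
  }
})

test_that("expected fraction follows the at-least-one-event closed form", {
  expect_equal(expected_fraction(0.003, 30), 1 - 0.997^30)
  expect_equal(round(100 * expected_fraction(0.003, 30), 1), 8.6)
  expect_equal(expected_fraction(0, 17), 0)
  expect_equal(expected_fraction(0.2, 0), 0)
  expect_error(expected_fraction(1.2, 3), "rate")
})

test_that("rate estimation inverts the forward relation", {
  expect_equal(round(100 * estimate_rate(0.086, 30), 1), 0.3)
  expect_equal(estimate_rate(0, 25), 0)
  expect_error(estimate_rate(1, 30), "unidentifiable")
  set.seed(72)
  for (rep in 1:50) {
    r <- runif(1, 1e-5, 0.1)
    g <- runif(1, 1, 50)
    expect_equal(estimate_rate(expected_fraction(r, g), g), r,
                 tolerance = 1e-12)
  }
  # strict monotonicity in both arguments
  rs <- seq(0.001, 0.05, length.out = 20)
  expect_true(all(diff(expected_fraction(rs, 30)) > 0))
  gs <- 1:40
  expect_true(all(diff(expected_fraction(0.01, gs)) > 0))
})

test_that("Fisher comparison matches hypergeometric enumeration", {
  expect_equal(compare_fractions(3, 35, 3, 35), 1)
  expect_lt(compare_fractions(0, 100, 100, 100), 1e-20)
  for (n1 in c(3, 5, 8)) {
    for (n2 in c(4, 7, 10)) {
      for (k1 in 0:n1) {
        for (k2 in 0:n2) {
          expect_equal(compare_fractions(k1, n1, k2, n2),
                       oracle_fisher(k1, n1, k2, n2),
                       tolerance = 1e-7,
                       info = paste(k1, n1, k2, n2))
        }
      }
    }
  }
})

test_that("background adjustment follows the independence form", {
  expect_equal(background_adjusted_fraction(0.086, 0), 0.086)
  expect_equal(background_adjusted_fraction(0.05, 0.05), 0)
  expect_equal(background_adjusted_fraction(0.086, 0.042),
               1 - (1 - 0.086) / (1 - 0.042))
  expect_equal(round(background_adjusted_fraction(0.086, 0.042), 4), 0.0459)
  expect_warning(out <- background_adjusted_fraction(0.02, 0.05),
                 "exceeds")
  expect_equal(out, 0)
  expect_error(background_adjusted_fraction(0.5, 1), "nothing observable")
})

test_that("with_rate attaches the inferred per-generation rate", {
  est <- with_rate(divergence_fraction(c(rep(TRUE, 3), rep(FALSE, 32))), 30)
  expect_equal(est$per_generation_rate,
               1 - (1 - 3 / 35)^(1 / 30), tolerance = 1e-12)
})
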