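test_that("population doublings follow the log2 dilution law", {
  expect_equal(population_doublings(2e5), 0)
  expect_equal(population_doublings(1.6e6), 3)
  expect_equal(population_doublings(1e5), -1)
  expect_error(population_doublings(0), "positive")
  expect_error(population_doublings(1e6, 0), "positive")
  # exact log law under doubling
  set.seed(81)
  d <- runif(20, 1e5, 1e7)
  for (k in c(1, 3, 7))
    expect_equal(population_doublings(d * 2^k),
                 population_doublings(d) + k, tolerance = 1e-12)
})

test_that("build_curve finds the senescence trough and recovery day", {
  d <- data.frame(day = 1:7,
                  density = c(4e6, 2e6, 8e5, 3e5, 6e5, 2e6, 8e6))
  cv <- build_curve(d)
  expect_equal(cv$trough_day, 4)
  expect_equal(cv$recovery_day, 5)
  expect_equal(cv$max_senescence_pd, sum(log2(d$density[1:4] / 2e5)))
  expect_true(all(!cv$days$shrinking[d$density > 2e5]))
})

test_that("constant density puts the trough on day 1", {
  d <- data.frame(day = 1:5, density = rep(1e6, 5))
  expect_equal(build_curve(d)$trough_day, 1)
})

test_that("trough day is invariant to uniform density rescaling", {
  set.seed(82)
  dens <- 2e5 * 2^runif(10, -1, 6)
  d <- data.frame(day = 1:10, density = dens)
  for (f in c(0.5, 2, 10))
    expect_equal(build_curve(transform(d, density = density * f))$trough_day,
                 build_curve(d)$trough_day)
})

test_that("non-consecutive days are rejected", {
  expect_error(build_curve(data.frame(day = c(1, 2, 4), density = 1e6)),
               "consecutive")
})

test_that("genotype comparison is a symmetric Welch test", {
  mk <- function(pds) lapply(pds, function(p) {
    structure(list(max_senescence_pd = p), class = "senescence_curve")
  })
  a <- mk(c(40.2, 39.1, 41.3, 40.8))
  b <- mk(c(60.5, 59.2, 61.1, 60.0, 58.8))
  cmp <- compare_genotypes(a, b)
  pd_a <- c(40.2, 39.1, 41.3, 40.8); pd_b <- c(60.5, 59.2, 61.1, 60.0, 58.8)
  expect_equal(cmp$p_value,
               t.test(pd_a, pd_b)$p.value, tolerance = 1e-12)
  expect_equal(cmp$p_value, compare_genotypes(b, a)$p_value)
  expect_equal(compare_genotypes(a, a)$p_value, 1)
  expect_error(compare_genotypes(a[1], b), "2 replicates")
})

test_that("Welch p-value agrees with a permutation oracle on small groups", {
  set.seed(83)
  x <- rnorm(8, 40, 2)
  y <- rnorm(8, 43, 2)
  mk <- function(v) lapply(v, function(p)
    structure(list(max_senescence_pd = p), class = "senescence_curve"))
  p_t <- compare_genotypes(mk(x), mk(y))$p_value
  p_perm <- oracle_perm_t(x, y, n_perm = 2e4)
  # agreement within Monte-Carlo and distributional error
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 2e4) + 0.02)
})

test_that("genotype summaries average by passage with sample-based SE", {
  prof <- senescence_profile("est2", n_replicates = 6, noise_sd = 0,
                             pd_sd = 1.5)
  dens <- emit_density_fixture(list(prof), seed = 9)
  curves <- build_curves(dens)
  sm <- summarize_genotype(curves)
  expect_equal(sm$n_replicates, 6)
  expect_equal(nrow(sm$per_passage), prof$n_days)
  # recompute one passage by hand
  day3 <- vapply(curves, function(cv) cv$days$cumulative_pd[3], 0)
  expect_equal(sm$per_passage$mean_cumulative_pd[3], mean(day3))
  expect_equal(sm$per_passage$se_cumulative_pd[3],
               sd(day3) / sqrt(length(day3)))
  # single replicate: SE undefined
  sm1 <- summarize_genotype(curves[1])
  expect_true(all(is.na(sm1$per_passage$se_cumulative_pd)))
  # identical replicates: SE zero
  sm0 <- summarize_genotype(rep(curves[1], 4))
  expect_true(all(sm0$per_passage$se_cumulative_pd == 0))
})
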