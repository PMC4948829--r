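test_that("a degenerate grammar with p2 = 1 emits pure TGG units", {
  set.seed(41)
  expect_identical(sample_telomere(12, repeat_grammar(0, 1, 0)),
                   "TGGTGGTGGTGG")
})

test_that("sampled telomeres belong to the TG1-3 grammar", {
  set.seed(42)
  for (rep in 1:20) {
    s <- sample_telomere(sample(10:300, 1))
    # possibly clipped mid-unit at the distal end
    expect_true(grepl("^(TG{1,3})*(T|TG{0,3})?$", s))
    expect_false(grepl("GGGG", s))
    expect_false(grepl("TT", s))
  }
})

test_that("unit frequencies match the grammar probabilities", {
  set.seed(43)
  s <- sample_telomere(2e5)
  units <- regmatches(s, gregexpr("TG{1,3}", s))[[1]]
  n <- length(units)
  p_hat <- tabulate(nchar(units) - 1L, 3L) / n
  p <- c(0.2, 0.5, 0.3)
  for (k in 1:3)
    expect_lt(abs(p_hat[k] - p[k]), 3 * sqrt(p[k] * (1 - p[k]) / n))
})

test_that("event-free lineages shorten by 3-4 nt per generation", {
  cfg <- sim_config(seed = 5, divergence_rate = 0, generations = 30)
  set.seed(5)
  init <- paste0(cfg$proximal_anchor, sample_telomere(270))
  lens <- replicate(60, nchar(evolve_lineage(init, cfg)$sequence))
  expect_true(all(lens >= 300 - 120 & lens <= 300 - 90))
  set.seed(6)
  lin <- evolve_lineage(init, cfg)
  expect_equal(nrow(lin$events), 0)
})

test_that("a forced divergence event is logged exactly once", {
  cfg <- sim_config(seed = 7, divergence_rate = 1, generations = 1)
  set.seed(7)
  init <- paste0(cfg$proximal_anchor, sample_telomere(270))
  lin <- evolve_lineage(init, cfg)
  expect_equal(sum(lin$events$type == "divergence"), 1)
  expect_gte(lin$events$position[1], nchar(cfg$proximal_anchor) + 1)
})

test_that("per-lineage event counts are Binomial(g, r)", {
  cfg <- sim_config(seed = 8, divergence_rate = 0.05, generations = 20)
  set.seed(8)
  init <- paste0(cfg$proximal_anchor, sample_telomere(270))
  counts <- replicate(1500, sum(evolve_lineage(init, cfg)$events$type ==
                                  "divergence"))
  g <- 20; r <- 0.05; n <- length(counts)
  expect_lt(abs(mean(counts) - g * r), 3 * sqrt(g * r * (1 - r) / n))
  # chi-square goodness of fit over the low count classes
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts >= 2))
  p <- c(dbinom(0, g, r), dbinom(1, g, r),
         1 - pbinom(1, g, r))
  chi <- sum((obs - n * p)^2 / (n * p))
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("large-scale incidence matches the closed form", {
  set.seed(9)
  inc <- simulate_divergence_incidence(1e5, 0.003, 30)
  f <- mean(inc)
  f0 <- expected_fraction(0.003, 30)
  expect_lt(abs(f - f0), 3 * sqrt(f0 * (1 - f0) / 1e5))
})

test_that("clone sets are byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 1234, clones_per_set = 10)
  s1 <- emit_clone_set(cfg)
  s2 <- emit_clone_set(cfg)
  expect_identical(s1$set$clones, s2$set$clones)
  expect_identical(s1$truth, s2$truth)
  s3 <- emit_clone_set(sim_config(seed = 1235, clones_per_set = 10))
  expect_false(identical(s1$set$clones$bases, s3$set$clones$bases))
  # file round-trip
  d <- tempfile()
  emit_clone_set(cfg, out_dir = d)
  sets <- read_clone_fasta(file.path(d, "clones.fasta"),
                           file.path(d, "samples.tsv"))
  expect_length(sets, 1)
  expect_identical(sets[[1]]$clones$bases, s1$set$clones$bases)
})

test_that("an event-free, error-free set is a pure shortening family", {
  cfg <- sim_config(seed = 31, divergence_rate = 0, clones_per_set = 12)
  sim <- emit_clone_set(cfg, technical_error_model(0, 0, 0))
  expect_false(any(sim$truth$true_diverged))
  calls <- call_set(sim$set)
  expect_false(any(calls$diverged))
  expect_equal(calls$undiverged_length_nt, calls$clone_length_nt)
})

test_that("truth records are consistent with emitted sequences", {
  cfg <- sim_config(seed = 32, divergence_rate = 0.05, clones_per_set = 40)
  sim <- emit_clone_set(cfg, technical_error_model(0.1, 0, 0))
  tr <- sim$truth
  expect_equal(tr$final_length_nt,
               nchar(sim$set$clones$bases))
  expect_true(all(tr$true_tail_nt[tr$true_diverged] ==
                    tr$final_length_nt[tr$true_diverged] -
                    tr$true_divergence_point[tr$true_diverged] + 1))
  expect_true(all(tr$true_tail_nt[!tr$true_diverged] == 0))
  expect_true(all(tr$event_type[!tr$true_diverged] == "none"))
})

test_that("density fixtures recover programmed troughs exactly at zero noise", {
  prof <- senescence_profile("est2", n_replicates = 8, trough_day = 7,
                             trough_pd = 40, pd_sd = 0, noise_sd = 0)
  dens <- emit_density_fixture(list(prof), seed = 3)
  curves <- build_curves(dens)
  expect_length(curves, 8)
  for (cv in curves) {
    expect_equal(cv$trough_day, 7)
    expect_equal(cv$max_senescence_pd, 40, tolerance = 1e-9)
  }
})

test_that("density fixtures are seeded deterministically", {
  prof <- senescence_profile("est2", n_replicates = 3, noise_sd = 0.2)
  d1 <- emit_density_fixture(list(prof), seed = 11)
  d2 <- emit_density_fixture(list(prof), seed = 11)
  d3 <- emit_density_fixture(list(prof), seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1$density, d3$density))
})

test_that("founder coordinates map onto reference coordinates", {
  truth <- data.frame(clone_id = c("a", "b"),
                      tech_indels = c("50:3;120:-2", ""))
  expect_equal(reference_coordinate(truth, "a", c(40, 60, 130)),
               c(40, 63, 131))
  expect_equal(reference_coordinate(truth, "b", c(40, 60)), c(40, 60))
  expect_error(reference_coordinate(truth, "zz", 1), "not found")
})
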