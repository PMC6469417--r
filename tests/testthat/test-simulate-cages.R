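test_that("cage_config rejects inconsistent parameters", {
  expect_error(cage_config(c("A", "B", "C"), 233, "relative_fitness", s = c(0, 0)),
               "length")
  expect_error(cage_config(c("A", "B", "C"), 233, "log_linear", s = 0),
               "exactly 2")
  expect_error(cage_config(c("A", "B"), 350, scoring_failure_prob = 1.2),
               "\\[0, 1\\]")
  expect_error(cage_config(c("A", "B"), 350, n_generations = 5,
                           sampling_generations = c(0, 9)),
               "sampling_generations")
  expect_error(cage_config(c("A", "A"), 350), "duplicate")
  expect_error(cage_config(c("A", "B"), 0), "positive")
})

test_that("neutral haplotypes at enormous census stay at founding frequencies", {
  cfg <- cage_config(c("A", "B", "C"), 233, "relative_fitness", s = c(0, 0, 0),
                     census_mean = 1e9, n_generations = 10,
                     sampling_generations = 0:10)
  tr <- simulate_cage(cfg, seed = 4, genotyping = FALSE)
  expect_true(all(abs(tr$true_frequencies - 1 / 3) < 1e-3))
})

test_that("log-linear mode without drift gives an exactly linear log frequency", {
  cfg <- cage_config(c("siI", "other"), 350, "log_linear", s = 0.062,
                     n_generations = 9)
  tr <- simulate_cage(cfg, drift = FALSE, genotyping = FALSE,
                      p0 = c(0.33, 0.67))
  lp <- log(tr$true_frequencies[, "siI"])
  fit <- lm(lp ~ tr$generations)
  expect_equal(unname(coef(fit)[2]), 0.062, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), log(0.33), tolerance = 1e-12)
})

test_that("relative-fitness update follows the closed-form single step", {
  cfg <- cage_config(c("A", "B"), 350, "relative_fitness", s = c(0.1, 0),
                     n_generations = 1, sampling_generations = c(0, 1))
  tr <- simulate_cage(cfg, drift = FALSE, genotyping = FALSE)
  expect_equal(unname(tr$true_frequencies["1", "A"]),
               exp(0.1) / (1 + exp(0.1)), tolerance = 1e-12)
})

test_that("a log-linear trajectory escaping (0,1) errors naming the generation", {
  cfg <- cage_config(c("A", "B"), 350, "log_linear", s = 0.2, n_generations = 9)
  expect_error(simulate_cage(cfg, drift = FALSE, genotyping = FALSE),
               "generation 4")
})

test_that("genotyping counts respect the attempted sample and degenerate frequencies", {
  expect_equal(sum(simulate_genotyping(c(0.4, 0.6), 93, failure_prob = 0, seed = 1)),
               93)
  counts <- simulate_genotyping(c(A = 1, B = 0), 92, failure_prob = 0.1, seed = 2)
  expect_equal(unname(counts["B"]), 0L)
  expect_equal(sum(counts), unname(counts["A"]))
  expect_error(simulate_genotyping(c(0.5, 0.4), 93), "sum to 1")
  # scored flies never exceed attempted
  for (i in 1:20)
    expect_lte(sum(simulate_genotyping(c(0.3, 0.7), 93, 0.0997, seed = i)), 93)
})

test_that("neutral drift variance matches the Wright-Fisher prediction", {
  N <- 100; tgen <- 5; nrep <- 2000
  cfg <- cage_config(c("A", "B"), 50, "relative_fitness", s = c(0, 0),
                     census_mean = N, n_generations = tgen,
                     sampling_generations = c(0, tgen))
  set.seed(31)
  pT <- replicate(nrep, {
    tr <- simulate_cage(cfg, genotyping = FALSE)
    tr$true_frequencies[tgen + 1, "A"]
  })
  expected <- 0.25 * (1 - (1 - 1 / N)^tgen)
  # Monte-Carlo tolerance: ~4 standard errors of a variance estimate
  expect_equal(var(pT), expected, tolerance = 4 * sqrt(2 / (nrep - 1)))
  expect_equal(mean(pT), 0.5, tolerance = 0.01)
})

test_that("identical config and seed give bit-identical experiments", {
  cfg <- cage_config(c("A", "B"), 350, "relative_fitness", s = c(-0.05, 0),
                     census_cv = 0.2, genotyping_attempted = 93,
                     scoring_failure_prob = 0.0997, n_cages = 2)
  e1 <- simulate_experiment(cfg, experiment_design(), seed = 12)
  e2 <- simulate_experiment(cfg, experiment_design(), seed = 12)
  expect_identical(e1, e2)
  e3 <- simulate_experiment(cfg, experiment_design(), seed = 13)
  expect_false(identical(e1$counts, e3$counts))
})

test_that("both phases start at exactly equal true frequencies", {
  cfg <- cage_config(c("A", "B", "C"), 233, "relative_fitness",
                     s = c(0.05, 0, -0.05), genotyping_attempted = 92,
                     scoring_failure_prob = 0.0692, n_cages = 2)
  ex <- simulate_experiment(cfg, experiment_design(), seed = 21)
  for (tr in c(ex$pre, ex$post))
    expect_equal(unname(tr$true_frequencies["0", ]), rep(1 / 3, 3),
                 tolerance = 1e-15)
  # the isofemale draw happened and is recorded per cage
  expect_equal(sum(ex$isofemales$n_isofemales), 2 * 48)
})

test_that("estimated starting frequencies scatter with binomial sampling noise", {
  k <- 3; n <- 92
  cfg <- cage_config(c("A", "B", "C"), 233, "relative_fitness", s = rep(0, 3),
                     n_generations = 1, sampling_generations = 0,
                     genotyping_attempted = n, scoring_failure_prob = 0)
  set.seed(77)
  p0_hat <- replicate(1000, {
    tr <- simulate_cage(cfg)
    tr$observed_counts["0", "A"] / sum(tr$observed_counts["0", ])
  })
  expect_equal(sd(p0_hat), sqrt((1 / k) * (1 - 1 / k) / n), tolerance = 0.08)
})

test_that("refounding fails loudly when a haplotype is extinct among isofemales", {
  cfg <- cage_config(c("A", "B", "C"), 233, "relative_fitness",
                     s = c(0, 0, -5), genotyping_attempted = 92, n_cages = 1)
  expect_error(simulate_experiment(cfg, experiment_design(), seed = 3),
               "extinct")
})

test_that("generated frequency vectors always sum to one", {
  cfg <- cage_config(c("A", "B", "C"), 233, "relative_fitness",
                     s = c(0.1, 0, -0.1), census_cv = 0.15, n_generations = 9)
  for (i in 1:10) {
    tr <- simulate_cage(cfg, seed = i, genotyping = FALSE)
    expect_true(all(abs(rowSums(tr$true_frequencies) - 1) < 1e-12))
    expect_true(all(tr$true_frequencies >= 0 & tr$true_frequencies <= 1))
  }
})
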