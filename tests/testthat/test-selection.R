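test_that("noiseless exponential decay is recovered exactly", {
  gens <- c(0, 1, 3, 5, 7, 9)
  ft <- freq_table_from_logfreq(list(cage1 = log(0.5) - 0.05 * gens), gens)
  fit <- fit_cage_slope(ft, "h")
  expect_equal(fit$s, -0.05, tolerance = 1e-12)
  expect_equal(fit$se_s, 0, tolerance = 1e-12)
  expect_equal(fit$n_points, 6L)
  # constant frequency has slope exactly zero
  flat <- freq_table_from_logfreq(list(cage1 = rep(log(0.4), 6)), gens)
  expect_equal(fit_cage_slope(flat, "h")$s, 0, tolerance = 1e-12)
})

test_that("three equally spaced points give the closed-form OLS slope", {
  ft <- freq_table_from_logfreq(list(cage1 = log(c(0.50, 0.45, 0.40))), 0:2)
  # frozen from the closed form (ln 0.40 - ln 0.50) / 2
  expect_equal(fit_cage_slope(ft, "h")$s, -0.111571775657105, tolerance = 1e-12)
})

test_that("zero-frequency generations are dropped and recorded, or continuity-corrected", {
  gens <- c(0, 1, 3, 5, 7, 9)
  ft <- freq_table_from_logfreq(list(cage1 = log(0.5) - 0.3 * gens), gens)
  ft$freq[ft$generation == 9] <- 0
  ft$n_scored <- 92L
  fit <- fit_cage_slope(ft, "h")
  expect_equal(fit$n_points, 5L)
  expect_equal(fit$dropped_points, "9")
  expect_equal(fit$s, -0.3, tolerance = 1e-12)
  cc <- fit_cage_slope(ft, "h", zero_policy = "continuity")
  expect_equal(cc$n_points, 6L)
  expect_equal(cc$dropped_points, "")
  # the corrected point pulls the slope toward the imputed 1/(2n)
  expect_false(isTRUE(all.equal(cc$s, fit$s)))
  # fewer than 3 usable points errors naming cage and haplotype
  short <- ft[ft$generation <= 3, ]
  short$freq[short$generation == 3] <- 0
  err <- tryCatch(fit_cage_slope(short, "h"), error = identity)
  expect_match(conditionMessage(err), "cage1")
  expect_match(conditionMessage(err), "h")
})

test_that("balanced designs make the overall coefficient the mean of per-cage slopes", {
  gens <- c(0, 1, 3, 5, 7, 9)
  set.seed(19)
  for (i in 1:5) {
    slopes <- rnorm(4, 0, 0.08)
    ys <- lapply(seq_along(slopes), function(ci)
      log(runif(1, 0.2, 0.4)) + slopes[ci] * gens + rnorm(6, 0, 0.05))
    names(ys) <- paste0("cage", 1:4)
    ft <- freq_table_from_logfreq(ys, gens)
    per_cage <- fit_cage_slopes(ft, "h")
    sm <- fit_haplotype_summary(ft, "h", n_draws = 0)
    expect_equal(sm$S, mean(per_cage$s), tolerance = 1e-8)
  }
})

test_that("identical cages show no repeatability; separated cages show near-total repeatability", {
  gens <- c(0, 1, 3, 5, 7, 9)
  y <- log(0.3) - 0.04 * gens
  same <- freq_table_from_logfreq(
    stats::setNames(rep(list(y), 4), paste0("cage", 1:4)), gens)
  sm <- fit_haplotype_summary(same, "h", n_draws = 0)
  expect_lt(sm$V_R, 1e-6)
  expect_lt(sm$lrt_stat, 1e-6)
  expect_gt(sm$lrt_p, 0.99)
  set.seed(23)
  apart <- freq_table_from_logfreq(stats::setNames(lapply(1:4, function(ci)
    ci * 10 - 0.04 * gens + rnorm(6, 0, 1e-3)), paste0("cage", 1:4)), gens)
  sm2 <- fit_haplotype_summary(apart, "h", n_draws = 0)
  expect_gt(sm2$V_R, 0.999)
  expect_lt(sm2$lrt_p, 1e-10)
})

test_that("repeatability test detects strong cage effects and matches the summary", {
  gens <- c(0, 1, 3, 5, 7, 9)
  set.seed(29)
  hits <- 0
  for (i in 1:200) {
    ys <- stats::setNames(lapply(1:4, function(ci)
      log(0.3) + rnorm(1, 0, 0.5) - 0.04 * gens + rnorm(6, 0, 0.05)),
      paste0("cage", 1:4))
    ft <- freq_table_from_logfreq(ys, gens)
    rt <- repeatability_test(ft, "h")
    hits <- hits + (rt$lrt_p < 0.05)
    if (i == 1) {
      sm <- fit_haplotype_summary(ft, "h", n_draws = 0)
      expect_equal(rt$V_R, sm$v / (sm$v + sm$r), tolerance = 1e-10)
    }
  }
  expect_gte(hits / 200, 0.95)
})

test_that("selection is called exactly when the interval excludes zero", {
  expect_equal(classify_selection(c(-0.092, -0.012)), "selection")
  expect_equal(classify_selection(c(-0.054, 0.054)), "drift_consistent")
  expect_equal(classify_selection(c(0.013, 0.054)), "selection")
  expect_equal(classify_selection(c(0, 0.05)), "drift_consistent")
  expect_error(classify_selection(c(0.1, -0.1)), "low > high")
})

test_that("bootstrap confidence intervals are seed-reproducible", {
  gens <- c(0, 1, 3, 5, 7, 9)
  set.seed(37)
  ys <- stats::setNames(lapply(1:4, function(ci)
    log(0.3) - 0.05 * gens + rnorm(6, 0, 0.1)), paste0("cage", 1:4))
  ft <- freq_table_from_logfreq(ys, gens)
  s1 <- fit_haplotype_summary(ft, "h", n_draws = 300, seed = 11)
  s2 <- fit_haplotype_summary(ft, "h", n_draws = 300, seed = 11)
  expect_identical(s1$ci, s2$ci)
  s3 <- fit_haplotype_summary(ft, "h", n_draws = 300, seed = 12)
  expect_false(identical(s1$ci, s3$ci))
})

test_that("haplotypes rank by mean final-generation frequency with flagged ties", {
  gens <- c(0, 6, 13)
  mk <- function(finalA, finalB, finalC) {
    rows <- list()
    for (cg in c("cage1", "cage2")) {
      for (h in c("siI", "sm21", "mau12")) {
        f0 <- c(siI = finalA, sm21 = finalB, mau12 = finalC)[h]
        rows[[paste(cg, h)]] <- data.frame(
          cage_id = cg, nuclear_background = "x", phase = "pre",
          generation = gens, haplotype = h, count = NA, n_scored = NA,
          freq = c(1 / 3, 1 / 3, f0), se = NA)
      }
    }
    do.call(rbind, rows)
  }
  r <- rank_haplotypes(mk(0.5, 0.3, 0.2))
  expect_equal(as.character(r), c("siI", "sm21", "mau12"))
  expect_false(attr(r, "ties"))
  r2 <- rank_haplotypes(mk(1 / 3, 1 / 3, 1 / 3))
  expect_equal(as.character(r2), c("mau12", "siI", "sm21"))
  expect_true(attr(r2, "ties"))
  two <- mk(0.7, 0.3, 0)[1:6, ]
  expect_equal(as.character(rank_haplotypes(two))[1], "siI")
  # mismatched final generations across cages cannot be ranked
  bad <- mk(0.5, 0.3, 0.2)
  bad <- bad[!(bad$cage_id == "cage2" & bad$generation == 13), ]
  expect_error(rank_haplotypes(bad), "final sampled generation")
})

test_that("phase comparisons flag sign and classification agreement", {
  gens_pre <- c(0, 1, 3, 5, 7, 9)
  set.seed(41)
  mk_sum <- function(slope, noise, seed) {
    ys <- stats::setNames(lapply(1:4, function(ci)
      log(0.3) + slope * gens_pre + rnorm(6, 0, noise)), paste0("cage", 1:4))
    fit_haplotype_summary(freq_table_from_logfreq(ys, gens_pre), "h",
                          n_draws = 400, seed = seed)
  }
  strong <- mk_sum(-0.05, 0.01, 1)
  # exact-null fixture: per-cage noise projected orthogonal to generation,
  # so the fitted overall slope is exactly zero and the CI brackets it
  ys0 <- stats::setNames(lapply(1:4, function(ci)
    log(0.3) + ci / 10 + resid(lm(rnorm(6, 0, 0.2) ~ gens_pre))), paste0("cage", 1:4))
  null_pre <- fit_haplotype_summary(freq_table_from_logfreq(ys0, gens_pre), "h",
                                    n_draws = 400, seed = 2)
  expect_equal(null_pre$classification, "drift_consistent")
  expect_equal(strong$classification, "selection")
  cmp <- compare_phases(strong, null_pre)
  expect_false(cmp$selection_agreement)
  same <- compare_phases(strong, strong)
  expect_true(same$sign_agreement && same$selection_agreement)
  other <- strong
  other$haplotype <- "different"
  expect_error(compare_phases(strong, other), "different haplotypes")
})

test_that("the summary table mirrors the published layout", {
  cfg <- cage_config(c("OreR", "Zm53"), 350, "relative_fitness",
                     s = c(-0.06, 0), genotyping_attempted = 93,
                     scoring_failure_prob = 0.0997, n_cages = 4)
  ex <- simulate_experiment(cfg, experiment_design(), seed = 55)
  f <- estimate_frequencies(ex$counts)
  tab <- selection_summary_table(f, n_draws = 200, seed = 7,
                                 focal = c(OreR = "OreR"))
  expect_setequal(names(tab),
                  c("nuclear_background", "haplotype", "phase", "cage_id",
                    "s_cage", "se_cage", "S_haplotype", "se_S", "ci_low",
                    "ci_high", "V_R", "lrt_p", "classification"))
  # one row per cage per phase, focal haplotype only in a 2-haplotype set
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$haplotype == "OreR"))
  expect_true(all(tab$ci_low <= tab$ci_high))
  expect_true(all(tab$V_R >= 0 & tab$V_R <= 1))
})
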