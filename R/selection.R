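#' Per-cage selection coefficient from a log-frequency regression
#'
#' The selection coefficient of a haplotype in one cage is the ordinary
#' least-squares slope of the natural log of its estimated frequency on
#' generation number (Dykhuizen-Hartl chemostat estimator applied to
#' discrete generations). Generations where the estimated frequency is 0
#' cannot enter the log regression; by default they are dropped and
#' recorded, or replaced by \code{1/(2 n_scored)} under the continuity
#' policy.
#'
#' @param freq a \code{"freq_table"} ([estimate_frequencies()]).
#' @param haplotype haplotype label to fit.
#' @param cage_id cage to fit; may be omitted when the table holds one cage.
#' @param phase phase to fit; may be omitted when the table holds one phase.
#' @param zero_policy \code{"drop"} (default) or \code{"continuity"}.
#' @return one-row data frame of class \code{"cage_fit"}: \code{cage_id},
#'   \code{phase}, \code{haplotype}, \code{s} (per generation), \code{se_s}
#'   (conventional OLS standard error), \code{n_points}, and
#'   \code{dropped_points} (comma-separated generations excluded for zero
#'   frequency).
#' @export
fit_cage_slope <- function(freq, haplotype, cage_id = NULL, phase = NULL,
                           zero_policy = c("drop", "continuity")) {
  zero_policy <- match.arg(zero_policy)
  d <- .subset_freq(freq, haplotype, cage_id, phase)
  if (length(unique(d$cage_id)) != 1L)
    stop("multiple cages present; pass cage_id (or use fit_cage_slopes)")
  .cage_slope(d, zero_policy)
}

.subset_freq <- function(freq, haplotype, cage_id = NULL, phase = NULL) {
  stopifnot(is.data.frame(freq))
  d <- freq[freq$haplotype == haplotype, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("haplotype '%s' not in the table", haplotype))
  if (!is.null(cage_id)) d <- d[d$cage_id %in% cage_id, , drop = FALSE]
  if (!is.null(phase)) d <- d[d$phase == phase, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows left after cage/phase filtering")
  if (length(unique(d$phase)) > 1L)
    stop("both phases present; pass phase = \"pre\" or \"post\"")
  d
}

.usable_points <- function(d, zero_policy) {
  dropped <- integer(0)
  if (any(d$freq == 0)) {
    if (zero_policy == "drop") {
      dropped <- d$generation[d$freq == 0]
      d <- d[d$freq > 0, , drop = FALSE]
    } else {
      if (any(is.na(d$n_scored[d$freq == 0])))
        stop("continuity correction needs n_scored for zero-frequency generations")
      d$freq[d$freq == 0] <- 1 / (2 * d$n_scored[d$freq == 0])
    }
  }
  list(points = d, dropped = dropped)
}

.cage_slope <- function(d, zero_policy) {
  u <- .usable_points(d, zero_policy)
  d <- u$points
  if (nrow(d) < 3L)
    stop(sprintf("cage %s, haplotype %s: only %d usable generation(s); need >= 3",
                 d$cage_id[1L], d$haplotype[1L], nrow(d)))
  fit <- stats::lm(log(freq) ~ generation, data = d)
  # exact trajectories are legitimate inputs; summary.lm warns on them
  sm <- .muffle_perfect_fit(summary(fit))$coefficients
  out <- data.frame(cage_id = d$cage_id[1L], phase = d$phase[1L],
                    haplotype = d$haplotype[1L],
                    s = unname(sm["generation", "Estimate"]),
                    se_s = unname(sm["generation", "Std. Error"]),
                    n_points = nrow(d),
                    dropped_points = paste(u$dropped, collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("cage_fit", "data.frame")
  out
}

#' Per-cage selection coefficients for every replicate cage
#'
#' @inheritParams fit_cage_slope
#' @return data frame with one [fit_cage_slope()] row per cage.
#' @export
fit_cage_slopes <- function(freq, haplotype, phase = NULL,
                            zero_policy = c("drop", "continuity")) {
  zero_policy <- match.arg(zero_policy)
  d <- .subset_freq(freq, haplotype, phase = phase)
  out <- do.call(rbind, lapply(split(d, d$cage_id, drop = TRUE),
                               .cage_slope, zero_policy = zero_policy))
  rownames(out) <- NULL
  out
}

#' Cross-cage selection summary for one haplotype
#'
#' Fits the random-intercept mixed model \eqn{\ln \hat p = \alpha + S
#' \cdot generation + u_{cage} + e} by maximum likelihood across all
#' replicate cages ([fit_random_intercept()]), and the pooled
#' fixed-effects-only model ([fit_pooled_ml()]). Reports the overall
#' selection coefficient \eqn{S} with a parametric-bootstrap 95\% CI
#' (simulate responses around the fitted fixed part using REML variance
#' components — the small-sample bias correction — refit by ML, take
#' percentile 2.5/97.5 of the refitted slopes),
#' the variance components \eqn{v} (between-cage) and \eqn{r} (residual),
#' the repeatability \eqn{V_R = v/(v+r)}, and the likelihood-ratio
#' statistic \eqn{2(\ell_{MEM} - \ell_{LM})} (floored at 0) with its
#' upper-tail chi-squared p-value on 1 d.f. The 1-d.f. reference is the
#' study's convention; it is conservative for a variance component on the
#' boundary (no 50:50 mixture correction applied).
#'
#' @inheritParams fit_cage_slope
#' @param n_draws parametric-bootstrap draws for the CI (default 5000);
#'   0 skips the CI (used when only \eqn{V_R} and the LRT are needed).
#' @param seed integer seed for the bootstrap draws.
#' @param level confidence level (default 0.95).
#' @return object of class \code{"haplotype_summary"}: a list with
#'   \code{haplotype}, \code{nuclear_background}, \code{phase}, \code{S},
#'   \code{se_S}, \code{ci} (low, high), \code{v}, \code{r}, \code{V_R},
#'   \code{lrt_stat}, \code{lrt_p}, \code{n_draws}, \code{n_cages},
#'   \code{classification} ("selection" iff the CI excludes zero).
#' @export
fit_haplotype_summary <- function(freq, haplotype, phase = NULL,
                                  n_draws = 5000, seed = NULL,
                                  zero_policy = c("drop", "continuity"),
                                  level = 0.95) {
  zero_policy <- match.arg(zero_policy)
  d <- .subset_freq(freq, haplotype, phase = phase)
  cages <- split(d, d$cage_id, drop = TRUE)
  if (length(cages) < 2L)
    stop(sprintf("haplotype %s: %d cage(s); need >= 2 for a cross-cage summary",
                 haplotype, length(cages)))
  pts <- lapply(cages, function(ci) {
    u <- .usable_points(ci, zero_policy)
    if (nrow(u$points) < 3L)
      stop(sprintf("cage %s, haplotype %s: only %d usable generation(s); need >= 3",
                   ci$cage_id[1L], haplotype, nrow(u$points)))
    u$points
  })
  dat <- do.call(rbind, pts)
  mem <- fit_random_intercept(log(dat$freq), dat$generation, dat$cage_id)
  lmf <- fit_pooled_ml(log(dat$freq), dat$generation)
  lrt <- max(0, 2 * (mem$logLik - lmf$logLik))
  vr <- if (mem$v + mem$r > 0) mem$v / (mem$v + mem$r) else 0
  ci <- c(NA_real_, NA_real_)
  if (n_draws > 0) {
    # simulate from REML variance components (ML components are biased low
    # with few cages and give underdispersed, anticonservative draws)
    vc <- .ri_reml_vc(mem$design, log(dat$freq))
    dsn <- mem$design
    mu <- as.numeric(dsn$X %*% mem$beta)
    slopes <- .with_seed(seed, {
      u <- matrix(stats::rnorm(dsn$G * n_draws, 0, sqrt(vc$v)), dsn$G, n_draws)
      e <- matrix(stats::rnorm(dsn$n * n_draws, 0, sqrt(vc$r)), dsn$n, n_draws)
      ystar <- mu + u[dsn$gi, , drop = FALSE] + e
      vapply(seq_len(n_draws),
             function(j) .ri_fit(dsn, ystar[, j])$beta[["slope"]],
             numeric(1))
    })
    ci <- unname(stats::quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  bg <- unique(d$nuclear_background)
  out <- list(haplotype = haplotype,
              nuclear_background = if (length(bg) == 1L) bg else NA_character_,
              phase = unique(d$phase),
              S = unname(mem$beta[2L]), se_S = unname(mem$se[2L]),
              ci = ci, v = mem$v, r = mem$r, V_R = vr,
              lrt_stat = lrt,
              lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
              n_draws = n_draws, n_cages = length(cages),
              level = level, mem = mem)
  out$classification <- if (all(is.finite(ci))) classify_selection(ci) else NA_character_
  class(out) <- "haplotype_summary"
  out
}

#' Repeatability of cage rank order across generations
#'
#' Tests whether cages keep their relative haplotype frequency across
#' generations by comparing the mixed model (random cage intercept) with
#' the pooled linear model, both fit by full maximum likelihood. Returns
#' the likelihood-ratio statistic (floored at 0), its chi-squared 1-d.f.
#' p-value, and the repeatability \eqn{V_R = v/(v+r)} (the intraclass
#' correlation of cage identity).
#'
#' @inheritParams fit_haplotype_summary
#' @return list with \code{lrt_stat}, \code{lrt_p}, \code{V_R}.
#' @export
repeatability_test <- function(freq, haplotype, phase = NULL,
                               zero_policy = c("drop", "continuity")) {
  s <- fit_haplotype_summary(freq, haplotype, phase = phase, n_draws = 0,
                             zero_policy = match.arg(zero_policy))
  list(lrt_stat = s$lrt_stat, lrt_p = s$lrt_p, V_R = s$V_R)
}

#' Classify a selection summary against the drift null
#'
#' A haplotype is under \code{"selection"} when its 95\% confidence
#' interval for the overall coefficient excludes zero, and
#' \code{"drift_consistent"} otherwise.
#'
#' @param x a \code{"haplotype_summary"} or a numeric \code{c(low, high)}.
#' @return \code{"selection"} or \code{"drift_consistent"}.
#' @export
classify_selection <- function(x) {
  ci <- if (inherits(x, "haplotype_summary")) x$ci else x
  if (length(ci) != 2L || !all(is.finite(ci))) stop("need a finite (low, high) interval")
  if (ci[1L] > ci[2L]) stop("interval has low > high")
  if (ci[1L] > 0 || ci[2L] < 0) "selection" else "drift_consistent"
}

#' Rank haplotypes by mean final-generation frequency
#'
#' Orders haplotypes by the across-cage mean of their estimated frequency
#' at the final sampled generation (descending). All cages must share the
#' same final sampled generation. Ties are broken lexicographically and
#' flagged via the \code{"ties"} attribute.
#'
#' @param freq a \code{"freq_table"}.
#' @param phase phase to rank; may be omitted when only one is present.
#' @return character vector of haplotype labels, best first, with
#'   attributes \code{"mean_freq"} and \code{"ties"}.
#' @export
rank_haplotypes <- function(freq, phase = NULL) {
  stopifnot(is.data.frame(freq))
  d <- freq
  if (!is.null(phase)) d <- d[d$phase == phase, , drop = FALSE]
  if (length(unique(d$phase)) > 1L)
    stop("both phases present; pass phase = \"pre\" or \"post\"")
  finals <- tapply(d$generation, d$cage_id, max)
  if (length(unique(finals)) > 1L)
    stop("cages end at different final sampled generations; cannot rank")
  fin <- d[d$generation == finals[[1L]], , drop = FALSE]
  means <- tapply(fin$freq, fin$haplotype, mean)
  ord <- order(-means, names(means))
  out <- names(means)[ord]
  attr(out, "mean_freq") <- as.numeric(means)[ord]
  attr(out, "ties") <- anyDuplicated(means) > 0L
  out
}

#' Compare a haplotype's selection summaries across phases
#'
#' @param pre,post \code{"haplotype_summary"} objects for the same
#'   haplotype (and nuclear background) in the pre- and post-perturbation
#'   phases.
#' @return list of class \code{"phase_comparison"} with
#'   \code{sign_agreement} (same sign of the overall coefficient) and
#'   \code{selection_agreement} (same selection classification).
#' @export
compare_phases <- function(pre, post) {
  stopifnot(inherits(pre, "haplotype_summary"), inherits(post, "haplotype_summary"))
  if (!identical(pre$haplotype, post$haplotype))
    stop("summaries are for different haplotypes")
  if (!identical(pre$nuclear_background, post$nuclear_background))
    stop("summaries are for different nuclear backgrounds")
  structure(list(haplotype = pre$haplotype,
                 nuclear_background = pre$nuclear_background,
                 pre = pre, post = post,
                 sign_agreement = sign(pre$S) == sign(post$S),
                 selection_agreement =
                   identical(pre$classification, post$classification)),
            class = "phase_comparison")
}

#' Selection summary table across haplotypes and phases
#'
#' Builds the per-cage plus overall selection-coefficient report: one row
#' per cage with its log-frequency slope and standard error, carrying the
#' cross-cage summary (overall coefficient, bootstrap CI, repeatability,
#' LRT p-value) on each row of its haplotype x phase block. In
#' 2-haplotype cage sets the complement haplotype is redundant (its
#' frequency is one minus the focal's), so only the focal haplotype is
#' reported; by default the first label in sorted order, or the one named
#' in \code{focal}.
#'
#' @param freq a \code{"freq_table"} (may hold several backgrounds).
#' @param n_draws,seed,zero_policy passed to [fit_haplotype_summary()].
#' @param focal optional named character vector mapping nuclear background
#'   to the focal haplotype of its 2-haplotype set.
#' @return data frame mirroring the published table layout: columns
#'   nuclear_background, haplotype, phase, cage_id, s_cage, se_cage,
#'   S_haplotype, se_S, ci_low, ci_high, V_R, lrt_p, classification.
#' @export
selection_summary_table <- function(freq, n_draws = 5000, seed = NULL,
                                    zero_policy = c("drop", "continuity"),
                                    focal = NULL) {
  zero_policy <- match.arg(zero_policy)
  rows <- list()
  draw_seed <- seed
  for (bg in unique(freq$nuclear_background)) {
    fb <- freq[freq$nuclear_background == bg, , drop = FALSE]
    haps <- sort(unique(fb$haplotype))
    if (length(haps) == 2L)
      haps <- if (!is.null(focal) && bg %in% names(focal)) focal[[bg]] else haps[1L]
    for (ph in intersect(c("pre", "post"), unique(fb$phase))) {
      for (h in haps) {
        per_cage <- fit_cage_slopes(fb, h, phase = ph, zero_policy = zero_policy)
        if (!is.null(draw_seed)) draw_seed <- draw_seed + 1L
        sm <- fit_haplotype_summary(fb, h, phase = ph, n_draws = n_draws,
                                    seed = draw_seed, zero_policy = zero_policy)
        rows[[length(rows) + 1L]] <- data.frame(
          nuclear_background = bg, haplotype = h, phase = ph,
          cage_id = per_cage$cage_id,
          s_cage = per_cage$s, se_cage = per_cage$se_s,
          S_haplotype = sm$S, se_S = sm$se_S,
          ci_low = sm$ci[1L], ci_high = sm$ci[2L],
          V_R = sm$V_R, lrt_p = sm$lrt_p,
          classification = sm$classification,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct exact log-linear frequency trajectories
#'
#' Builds a frequency table whose per-cage trajectories are exactly
#' \eqn{p_c(t) = p_c(0) e^{s_c t}} — the noiseless generative model behind
#' the log-frequency regression estimator. Used to verify the
#' balanced-design identity (with equal generation sets per cage, the
#' mixed-model overall coefficient equals the unweighted mean of the
#' per-cage slopes) against published per-cage values.
#'
#' @param slopes per-cage log-frequency slopes (one cage per element).
#' @param generations sampled generations (shared by all cages).
#' @param p0 per-cage starting frequencies; by default distinct values in
#'   (0.25, 0.4), rescaled so increasing trajectories stay below 1.
#' @param haplotype,phase,nuclear_background labels for the table.
#' @return data frame of class \code{"freq_table"} (no count/SE columns).
#' @export
log_linear_frequency_table <- function(slopes, generations = c(0, 1, 3, 5, 7, 9),
                                       p0 = NULL,
                                       haplotype = "focal", phase = "pre",
                                       nuclear_background = "sim") {
  n <- length(slopes)
  tmax <- max(generations)
  if (is.null(p0)) {
    base <- seq(0.25, 0.4, length.out = n)
    growth <- pmax(1, exp(slopes * tmax))
    p0 <- base * 0.95 / growth
  }
  stopifnot(length(p0) == n, all(p0 > 0))
  rows <- lapply(seq_len(n), function(ci) {
    f <- p0[ci] * exp(slopes[ci] * generations)
    data.frame(cage_id = sprintf("cage%d", ci),
               nuclear_background = nuclear_background, phase = phase,
               generation = as.integer(generations), haplotype = haplotype,
               count = NA_integer_, n_scored = NA_integer_,
               freq = f, se = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("freq_table", "data.frame")
  out
}

#' @export
print.haplotype_summary <- function(x, ...) {
  cat(sprintf("Haplotype %s (%s phase%s): %d cages\n", x$haplotype, x$phase,
              if (is.na(x$nuclear_background)) ""
              else paste0(", ", x$nuclear_background, " nDNA"), x$n_cages))
  cat(sprintf("  S = %.4f (SE %.4f) per generation\n", x$S, x$se_S))
  if (all(is.finite(x$ci)))
    cat(sprintf("  %d%% CI [%.4f, %.4f] (%d bootstrap draws) -> %s\n",
                round(100 * x$level), x$ci[1L], x$ci[2L], x$n_draws,
                x$classification))
  cat(sprintf("  V_R = %.3f (v = %.3g, r = %.3g); LRT = %.3f, p = %.3g\n",
              x$V_R, x$v, x$r, x$lrt_stat, x$lrt_p))
  invisible(x)
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("Phase comparison for %s (%s nDNA):\n", x$haplotype,
              x$nuclear_background))
  cat(sprintf("  S pre = %.4f (%s), S post = %.4f (%s)\n",
              x$pre$S, x$pre$classification, x$post$S, x$post$classification))
  cat(sprintf("  sign agreement: %s; selection-class agreement: %s\n",
              x$sign_agreement, x$selection_agreement))
  invisible(x)
}
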