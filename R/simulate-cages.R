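#' Configuration for a simulated population cage
#'
#' Bundles and validates the parameters of one cage treatment: competing
#' mtDNA haplotypes founded at equal numbers, discrete non-overlapping
#' generations, multinomial (Wright-Fisher) drift at a finite census size,
#' and genotyping of a fixed number of flies at the sampled generations
#' with per-fly scoring failures.
#'
#' Two selection modes are supported. \code{"relative_fitness"} updates
#' frequencies as \eqn{p_i' \propto p_i e^{s_i}} before drift, the standard
#' discrete-generation haploid selection model. \code{"log_linear"}
#' (2 haplotypes only) forces the focal (first) haplotype's expected
#' log-frequency to move by exactly \code{s} per generation,
#' \eqn{p' = p e^{s}}, so that the log-frequency regression estimator is
#' exactly unbiased; it is the generative counterpart of the estimator.
#'
#' @param haplotypes character vector of 2 or 3 haplotype labels.
#' @param founders_per_haplotype flies of each haplotype at founding
#'   (350 in 2-haplotype cages, 233 in 3-haplotype cages).
#' @param selection_mode \code{"relative_fitness"} or \code{"log_linear"}.
#' @param s per-haplotype, per-generation selection coefficients. A scalar
#'   is recycled to all haplotypes in relative-fitness mode (scalar 0 =
#'   neutrality); in log-linear mode a scalar applies to the first (focal)
#'   haplotype.
#' @param census_mean target adult census size per generation (~700).
#' @param census_cv coefficient of variation of census size across
#'   generations; 0 keeps the census fixed at \code{census_mean}.
#' @param n_generations number of generations after founding.
#' @param sampling_generations generations (within \code{0:n_generations})
#'   at which flies are genotyped.
#' @param genotyping_attempted flies sampled for genotyping per
#'   cage-generation (93 in 2-haplotype cages, 92 in 3-haplotype cages).
#' @param scoring_failure_prob probability an attempted fly yields no
#'   genotype (independent per fly).
#' @param n_cages replicate cages per treatment.
#' @return validated list of class \code{"cage_config"}.
#' @export
cage_config <- function(haplotypes,
                        founders_per_haplotype,
                        selection_mode = c("relative_fitness", "log_linear"),
                        s = 0,
                        census_mean = 700,
                        census_cv = 0,
                        n_generations = 9,
                        sampling_generations = c(0, 1, 3, 5, 7, 9),
                        genotyping_attempted = 92,
                        scoring_failure_prob = 0,
                        n_cages = 4) {
  selection_mode <- match.arg(selection_mode)
  k <- length(haplotypes)
  if (!k %in% c(2L, 3L)) stop("need 2 or 3 haplotype labels")
  if (anyDuplicated(haplotypes)) stop("duplicate haplotype labels")
  if (selection_mode == "log_linear") {
    if (k != 2L) stop("log_linear mode allows exactly 2 haplotypes")
    if (length(s) == 1L) s <- c(s, 0)
  }
  if (length(s) == 1L) s <- rep(s, k)
  if (length(s) != k)
    stop(sprintf("s has length %d but there are %d haplotypes", length(s), k))
  if (founders_per_haplotype <= 0 || census_mean <= 0 || genotyping_attempted <= 0)
    stop("founders_per_haplotype, census_mean and genotyping_attempted must be positive")
  if (scoring_failure_prob < 0 || scoring_failure_prob > 1)
    stop("scoring_failure_prob must lie in [0, 1]")
  if (census_cv < 0) stop("census_cv must be non-negative")
  if (n_generations < 1) stop("n_generations must be at least 1")
  sampling_generations <- sort(unique(as.integer(sampling_generations)))
  if (any(sampling_generations < 0) || any(sampling_generations > n_generations))
    stop("sampling_generations must lie within 0..n_generations")
  structure(list(
    haplotypes = as.character(haplotypes),
    founders_per_haplotype = as.integer(founders_per_haplotype),
    selection_mode = selection_mode,
    s = as.numeric(s),
    census_mean = as.integer(census_mean),
    census_cv = census_cv,
    n_generations = as.integer(n_generations),
    sampling_generations = sampling_generations,
    genotyping_attempted = as.integer(genotyping_attempted),
    scoring_failure_prob = scoring_failure_prob,
    n_cages = as.integer(n_cages)
  ), class = "cage_config")
}

#' Genotype a sample of flies from known haplotype frequencies
#'
#' Emulates the PCR-RFLP scoring step: \code{n_attempted} flies are drawn,
#' each independently fails to score with probability \code{failure_prob},
#' and the scored flies are assigned haplotypes multinomially from the true
#' frequencies.
#'
#' @param true_frequencies haplotype frequencies (must sum to 1 within 1e-9).
#' @param n_attempted flies sampled for genotyping.
#' @param failure_prob per-fly probability of a scoring failure.
#' @param seed optional integer seed; the global RNG state is restored.
#' @return named integer vector of scored-fly counts per haplotype; the sum
#'   is the realized number of scored flies (at most \code{n_attempted}).
#' @export
simulate_genotyping <- function(true_frequencies, n_attempted,
                                failure_prob = 0, seed = NULL) {
  if (abs(sum(true_frequencies) - 1) > 1e-9)
    stop("true_frequencies must sum to 1 (within 1e-9)")
  if (any(true_frequencies < 0)) stop("negative frequency")
  if (n_attempted <= 0) stop("n_attempted must be positive")
  .with_seed(seed, {
    scored <- stats::rbinom(1L, n_attempted, 1 - failure_prob)
    counts <- as.integer(stats::rmultinom(1L, scored, true_frequencies))
    names(counts) <- names(true_frequencies)
    counts
  })
}

#' Simulate one population cage
#'
#' Runs a single cage forward from equal founding numbers: selection update
#' per \code{config$selection_mode}, then (optionally) Wright-Fisher drift
#' as a multinomial draw of the next generation's census from the
#' post-selection frequencies. Genotyping observations are generated at the
#' configured sampling generations via [simulate_genotyping()].
#'
#' @param config a [cage_config()].
#' @param cage_id label for this cage.
#' @param seed optional integer seed; identical \code{(config, seed)} give
#'   bit-identical trajectories.
#' @param drift logical; \code{FALSE} runs the deterministic trajectory
#'   (infinite-population limit), used to validate estimator fidelity.
#' @param genotyping logical; \code{FALSE} skips the observation layer.
#' @param p0 optional founding frequencies overriding the equal-founding
#'   default (must sum to 1); used for recovery studies that start a focal
#'   haplotype away from 1/k.
#' @return object of class \code{"cage_trajectory"}: \code{generations},
#'   \code{true_frequencies} (generations x haplotypes matrix, rows sum to
#'   1), \code{census_sizes}, and \code{observed_counts} (sampled
#'   generations x haplotypes) when genotyping is on.
#' @export
simulate_cage <- function(config, cage_id = "cage1", seed = NULL,
                          drift = TRUE, genotyping = TRUE, p0 = NULL) {
  stopifnot(inherits(config, "cage_config"))
  .with_seed(seed, .simulate_cage_impl(config, cage_id, drift, genotyping, p0))
}

.simulate_cage_impl <- function(config, cage_id, drift, genotyping, p0 = NULL) {
  k <- length(config$haplotypes)
  if (!is.null(p0)) {
    if (length(p0) != k || abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
      stop("p0 must be one frequency per haplotype, summing to 1")
  } else p0 <- rep(1 / k, k)
  tmax <- config$n_generations
  p <- matrix(NA_real_, tmax + 1L, k,
              dimnames = list(0:tmax, config$haplotypes))
  p[1L, ] <- p0
  census <- c(k * config$founders_per_haplotype,
              .draw_census(tmax, config$census_mean, config$census_cv))
  for (t in seq_len(tmax)) {
    psel <- .select_step(p[t, ], config, generation = t)
    p[t + 1L, ] <- if (drift) {
      as.integer(stats::rmultinom(1L, census[t + 1L], psel)) / census[t + 1L]
    } else psel
  }
  obs <- NULL
  if (genotyping) {
    obs <- t(vapply(config$sampling_generations, function(gen) {
      simulate_genotyping(p[gen + 1L, ], config$genotyping_attempted,
                          config$scoring_failure_prob)
    }, integer(k)))
    dimnames(obs) <- list(config$sampling_generations, config$haplotypes)
  }
  structure(list(cage_id = cage_id,
                 generations = 0:tmax,
                 true_frequencies = p,
                 census_sizes = census,
                 sampling_generations = config$sampling_generations,
                 observed_counts = obs,
                 config = config),
            class = "cage_trajectory")
}

.select_step <- function(p, config, generation) {
  if (config$selection_mode == "relative_fitness") {
    w <- p * exp(config$s)
    w / sum(w)
  } else {
    pf <- p[1L] * exp(config$s[1L])
    if (pf <= 0 || pf >= 1)
      stop(sprintf(
        "log_linear trajectory leaves (0,1) at generation %d (focal frequency %.6g)",
        generation, pf))
    c(pf, 1 - pf)
  }
}

# Census sizes fluctuate log-normally around census_mean with coefficient of
# variation census_cv (independent across generations); cv = 0 is fixed.
.draw_census <- function(n, mean, cv) {
  if (cv == 0) return(rep(as.integer(mean), n))
  sdlog <- sqrt(log1p(cv^2))
  pmax(2L, as.integer(round(stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog))))
}

#' Design of the perturbation-reperturbation experiment
#'
#' The two-phase schedule: a pre-perturbation phase from equal founding
#' numbers, an isofemale reperturbation event (females sampled from the
#' final pre-phase population, genotyped, and their offspring pooled), and
#' a post-reperturbation phase re-founded at equal haplotype numbers.
#'
#' @param pre_generations length of the pre-perturbation phase (9).
#' @param post_generations length of the post-reperturbation phase (13).
#' @param pre_sampling generations genotyped pre-perturbation (0,1,3,5,7,9).
#' @param post_sampling generations genotyped post-reperturbation (0,6,13).
#' @param n_isofemales mated females isolated at reperturbation (48).
#' @param refound_equal re-found the post phase at equal haplotype numbers
#'   regardless of the pre-phase outcome (the study's design).
#' @return validated list of class \code{"experiment_design"}.
#' @export
experiment_design <- function(pre_generations = 9,
                              post_generations = 13,
                              pre_sampling = c(0, 1, 3, 5, 7, 9),
                              post_sampling = c(0, 6, 13),
                              n_isofemales = 48,
                              refound_equal = TRUE) {
  if (n_isofemales < 1) stop("n_isofemales must be positive")
  if (any(pre_sampling < 0) || any(pre_sampling > pre_generations))
    stop("pre_sampling outside the pre-perturbation phase")
  if (any(post_sampling < 0) || any(post_sampling > post_generations))
    stop("post_sampling outside the post-perturbation phase")
  structure(list(pre_generations = as.integer(pre_generations),
                 post_generations = as.integer(post_generations),
                 pre_sampling = sort(unique(as.integer(pre_sampling))),
                 post_sampling = sort(unique(as.integer(post_sampling))),
                 n_isofemales = as.integer(n_isofemales),
                 refound_equal = isTRUE(refound_equal)),
            class = "experiment_design")
}

#' Simulate the full perturbation-reperturbation experiment
#'
#' Runs \code{config$n_cages} replicate cages through both phases. At
#' reperturbation, \code{n_isofemales} mated females are drawn from each
#' cage with haplotypes multinomial in the final pre-phase *estimated*
#' frequencies (the genotyped sample, not the true frequencies, mirroring
#' how the study identified isofemale haplotypes); the post phase is then
#' re-founded at equal haplotype numbers. Only the maternal haplotype
#' matters for mtDNA, so mates are not modeled.
#'
#' @param config a [cage_config()]; \code{n_generations} and
#'   \code{sampling_generations} are taken from \code{design} per phase.
#' @param design an [experiment_design()].
#' @param seed integer seed (required: the experiment is stochastic).
#' @param nuclear_background label recorded in the output table.
#' @return list with \code{counts} (long-format genotype-count data frame
#'   with columns cage_id, nuclear_background, phase, generation, haplotype,
#'   count), \code{isofemales} (haplotype counts among the sampled females
#'   per cage), and the per-cage \code{pre}/\code{post} trajectories.
#' @export
simulate_experiment <- function(config, design = experiment_design(),
                                seed, nuclear_background = "OreR") {
  stopifnot(inherits(config, "cage_config"), inherits(design, "experiment_design"))
  .with_seed(seed, .simulate_experiment_impl(config, design, nuclear_background))
}

.simulate_experiment_impl <- function(config, design, nuclear_background) {
  pre_cfg <- config
  pre_cfg$n_generations <- design$pre_generations
  pre_cfg$sampling_generations <- design$pre_sampling
  post_cfg <- config
  post_cfg$n_generations <- design$post_generations
  post_cfg$sampling_generations <- design$post_sampling

  pre <- list(); post <- list(); iso <- list(); rows <- list()
  for (i in seq_len(config$n_cages)) {
    id <- sprintf("cage%d", i)
    tr_pre <- .simulate_cage_impl(pre_cfg, id, drift = TRUE, genotyping = TRUE)
    last <- as.character(max(design$pre_sampling))
    obs <- tr_pre$observed_counts[last, ]
    p_hat <- obs / sum(obs)
    iso_counts <- as.integer(stats::rmultinom(1L, design$n_isofemales, p_hat))
    names(iso_counts) <- config$haplotypes
    if (design$refound_equal && any(iso_counts == 0L))
      stop(sprintf(
        "haplotype(s) %s extinct among the %d isofemales of %s: cannot re-found at equal numbers",
        paste(config$haplotypes[iso_counts == 0L], collapse = ", "),
        design$n_isofemales, id))
    tr_post <- .simulate_cage_impl(post_cfg, id, drift = TRUE, genotyping = TRUE)
    pre[[id]] <- tr_pre; post[[id]] <- tr_post; iso[[id]] <- iso_counts
    rows[[id]] <- rbind(
      .counts_to_rows(tr_pre, id, nuclear_background, "pre"),
      .counts_to_rows(tr_post, id, nuclear_background, "post"))
  }
  counts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  iso_df <- data.frame(cage_id = rep(names(iso), each = length(config$haplotypes)),
                       haplotype = rep(config$haplotypes, length(iso)),
                       n_isofemales = unlist(iso, use.names = FALSE),
                       row.names = NULL)
  list(counts = counts, isofemales = iso_df, pre = pre, post = post)
}

.counts_to_rows <- function(traj, cage_id, nuclear_background, phase) {
  obs <- traj$observed_counts
  k <- ncol(obs)
  data.frame(cage_id = cage_id,
             nuclear_background = nuclear_background,
             phase = phase,
             generation = rep(as.integer(rownames(obs)), each = k),
             haplotype = rep(colnames(obs), nrow(obs)),
             count = as.integer(t(obs)),
             row.names = NULL)
}

#' @export
print.cage_trajectory <- function(x, ...) {
  cat(sprintf("Cage trajectory '%s': %d haplotypes, generations 0..%d\n",
              x$cage_id, ncol(x$true_frequencies), max(x$generations)))
  cat("Final true frequencies:\n")
  print(round(x$true_frequencies[nrow(x$true_frequencies), ], 4))
  invisible(x)
}
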