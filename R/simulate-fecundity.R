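#' Specification for a simulated non-competitive fecundity assay
#'
#' One isofemale per vial lays for a fixed period; the response is the
#' total number of eclosed offspring. Counts are generated per genotype
#' group around the group mean with negative-binomial overdispersion.
#'
#' @param group_means named numeric vector: expected offspring per
#'   isofemale for each genotype (mtDNA haplotype) label.
#' @param dispersion NB2 overdispersion parameter \eqn{d}: the count
#'   variance is \eqn{\mu + d\mu^2}. \code{d = 0} is the deterministic
#'   limit and yields every count equal to the rounded mean (note this is
#'   not the Poisson limit, which is approached as \eqn{d \to 0^+}).
#' @param n_per_group isofemales per genotype group.
#' @return validated list of class \code{"fecundity_spec"}.
#' @export
fecundity_spec <- function(group_means, dispersion = 0.33, n_per_group = 58) {
  if (is.null(names(group_means)) || any(names(group_means) == ""))
    stop("group_means must be a named vector (genotype labels)")
  if (any(group_means < 0)) stop("group means must be non-negative")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (n_per_group < 1) stop("n_per_group must be at least 1")
  structure(list(group_means = group_means, dispersion = dispersion,
                 n_per_group = as.integer(n_per_group)),
            class = "fecundity_spec")
}

#' Simulate an isofemale fecundity table
#'
#' @param spec a [fecundity_spec()].
#' @param seed optional integer seed.
#' @param nuclear_background,cage_id labels recorded in the output.
#' @return data frame with one row per isofemale: \code{isofemale_id},
#'   \code{cage_id}, \code{nuclear_background}, \code{mtdna_haplotype},
#'   \code{offspring_count} (non-negative integer).
#' @export
simulate_fecundity <- function(spec, seed = NULL,
                               nuclear_background = "OreR", cage_id = "cage1") {
  stopifnot(inherits(spec, "fecundity_spec"))
  .with_seed(seed, {
    rows <- lapply(names(spec$group_means), function(h) {
      mu <- spec$group_means[[h]]
      counts <- if (spec$dispersion == 0) {
        rep(as.integer(round(mu)), spec$n_per_group)
      } else {
        stats::rnbinom(spec$n_per_group, size = 1 / spec$dispersion, mu = mu)
      }
      data.frame(mtdna_haplotype = h, offspring_count = as.integer(counts),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- data.frame(isofemale_id = sprintf("iso%03d", seq_len(nrow(out))),
                      cage_id = cage_id,
                      nuclear_background = nuclear_background,
                      out, stringsAsFactors = FALSE)
    out
  })
}

#' Read an isofemale fecundity table
#'
#' Required columns (case-insensitive): \code{isofemale_id},
#' \code{nuclear_background}, \code{mtdna_haplotype},
#' \code{offspring_count}; \code{cage_id} is optional. If
#' \code{mtdna_species} is absent it is derived from the haplotype map.
#'
#' @param path CSV file path.
#' @param species_map haplotype-to-species map, see [default_species_map()].
#' @return validated data frame with an \code{mtdna_species} column.
#' @export
read_fecundity <- function(path, species_map = default_species_map()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("isofemale_id", "nuclear_background", "mtdna_haplotype",
            "offspring_count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("fecundity file missing column(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- which(is.na(df$offspring_count) | df$offspring_count < 0)
  if (length(bad))
    stop(sprintf("offspring_count must be non-negative (rows %s)",
                 paste(bad, collapse = ", ")))
  if (!"mtdna_species" %in% names(df))
    df <- add_mtdna_species(df, species_map)
  df
}
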