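#' Default mtDNA haplotype-to-species map
#'
#' The haplotypes studied here fall into two species groups: \emph{D.
#' melanogaster} mtDNAs (OreR, Zm53) and the \emph{D. simulans} clade
#' (siI, sm21, mau12). Extendable for new haplotypes by passing a longer
#' named vector wherever a \code{species_map} argument is accepted.
#'
#' @return named character vector: haplotype label -> species label.
#' @export
default_species_map <- function() {
  c(OreR = "melanogaster", Zm53 = "melanogaster",
    siI = "simulans", sm21 = "simulans", mau12 = "simulans")
}

#' Derive the mtDNA species column from haplotype labels
#'
#' @param records fecundity data frame with an \code{mtdna_haplotype} column.
#' @param species_map named map, haplotype -> species.
#' @return \code{records} with an \code{mtdna_species} column appended.
#' @export
add_mtdna_species <- function(records, species_map = default_species_map()) {
  unknown <- setdiff(unique(records$mtdna_haplotype), names(species_map))
  if (length(unknown))
    stop(sprintf("haplotype(s) with no species mapping: %s",
                 paste(unknown, collapse = ", ")))
  records$mtdna_species <- unname(species_map[records$mtdna_haplotype])
  records
}

# Shared OLS machinery for the fecundity contrasts: treatment coding
# against `reference`, two-sided t-tests per coefficient, and a one-way
# ANOVA decomposition with R^2.
.fecundity_lm <- function(records, term_col, reference) {
  levels_present <- unique(records[[term_col]])
  if (!reference %in% levels_present)
    stop(sprintf("reference level '%s' absent from the data", reference))
  if (length(levels_present) < 2L)
    stop("need at least 2 factor levels")
  n_by <- table(records[[term_col]])
  small <- names(n_by)[n_by < 2L]
  if (length(small))
    stop(sprintf("level(s) with fewer than 2 records: %s",
                 paste(small, collapse = ", ")))
  records$.term <- stats::relevel(factor(records[[term_col]]), ref = reference)
  fit <- stats::lm(offspring_count ~ .term, data = records)
  sm <- .muffle_perfect_fit(summary(fit))$coefficients
  coefs <- data.frame(
    level = sub("^\\.term", "", rownames(sm)[-1L]),
    beta = unname(sm[-1L, "Estimate"]),
    se = unname(sm[-1L, "Std. Error"]),
    t = unname(sm[-1L, "t value"]),
    p = unname(sm[-1L, "Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  av <- .muffle_perfect_fit(stats::anova(fit))
  ss_eff <- av$`Sum Sq`[1L]; ss_res <- av$`Sum Sq`[2L]
  # degenerate data (all responses identical leave only rounding dust in
  # the sums of squares): define a null effect
  eps <- 1e-10 * max(1, sum(records$offspring_count^2))
  degenerate <- ss_eff < eps
  f_stat <- if (degenerate) 0 else av$`F value`[1L]
  p_f <- if (degenerate) 1 else av$`Pr(>F)`[1L]
  r2 <- if (degenerate) 0 else ss_eff / (ss_eff + ss_res)
  structure(list(
    term = term_col,
    reference = reference,
    intercept = unname(sm[1L, "Estimate"]),
    intercept_se = unname(sm[1L, "Std. Error"]),
    coefficients = coefs,
    anova = data.frame(df_effect = av$Df[1L], df_resid = av$Df[2L],
                       ss_effect = ss_eff, ss_resid = ss_res,
                       r_squared = r2, F = f_stat, p = p_f),
    n = nrow(records),
    fit = fit), class = "fecundity_fit")
}

#' Haplotype effects on isofemale offspring number
#'
#' Ordinary least squares of offspring count on mtDNA haplotype within one
#' nuclear background x mtDNA species set, with treatment coding against a
#' reference haplotype (the study's convention: mau12 for \emph{D.
#' simulans}-type sets, OreR for \emph{D. melanogaster}-type sets).
#' Reports per-haplotype coefficients with two-sided t-tests, and the
#' one-way ANOVA decomposition (df, sums of squares, R-squared, F, p).
#' Counts are modeled on the raw scale, preserving comparability with the
#' published linear-model tables.
#'
#' @param records fecundity rows for one nuclear background x species set.
#' @param reference reference haplotype label.
#' @return object of class \code{"fecundity_fit"}.
#' @export
fit_haplotype_model <- function(records, reference) {
  .fecundity_lm(records, "mtdna_haplotype", reference)
}

#' mtDNA species contrast on isofemale offspring number
#'
#' Two-level linear model of offspring count on mtDNA species
#' (\emph{D. melanogaster} vs \emph{D. simulans} clade) within one nuclear
#' background, with the conspecific (melanogaster) group as reference.
#'
#' @param records fecundity rows for one nuclear background (both species
#'   present).
#' @param species_map haplotype-to-species map used when the species
#'   column is absent.
#' @return object of class \code{"fecundity_fit"}.
#' @export
fit_species_contrast <- function(records, species_map = default_species_map()) {
  if (!"mtdna_species" %in% names(records))
    records <- add_mtdna_species(records, species_map)
  if (length(unique(records$mtdna_species)) < 2L)
    stop("only one mtDNA species present; the contrast needs both")
  .fecundity_lm(records, "mtdna_species", "melanogaster")
}

#' @export
print.fecundity_fit <- function(x, ...) {
  cat(sprintf("Fecundity linear model (%s), n = %d\n", x$term, x$n))
  cat(sprintf("  intercept %.2f (%s)\n", x$intercept, x$reference))
  for (i in seq_len(nrow(x$coefficients)))
    cat(sprintf("  %s: beta = %.3f (SE %.3f), t = %.2f, p = %.3g\n",
                x$coefficients$level[i], x$coefficients$beta[i],
                x$coefficients$se[i], x$coefficients$t[i],
                x$coefficients$p[i]))
  a <- x$anova
  cat(sprintf("  ANOVA: F(%d, %d) = %.3f, R2 = %.3f, p = %.3g\n",
              a$df_effect, a$df_resid, a$F, a$r_squared, a$p))
  invisible(x)
}

#' Flatten fecundity fits into a report table
#'
#' @param fits named list of \code{"fecundity_fit"} objects; names label
#'   the rows (e.g., "simulans.OreR").
#' @return data frame with one row per non-reference coefficient, carrying
#'   the ANOVA block of its model.
#' @export
fecundity_report <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, reference = f$reference,
               intercept = f$intercept,
               level = f$coefficients$level,
               beta = f$coefficients$beta, se = f$coefficients$se,
               t = f$coefficients$t, p = f$coefficients$p,
               df_effect = f$anova$df_effect, df_resid = f$anova$df_resid,
               ss_effect = f$anova$ss_effect, ss_resid = f$anova$ss_resid,
               r_squared = f$anova$r_squared, F = f$anova$F,
               p_anova = f$anova$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
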