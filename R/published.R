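#' Published per-cage selection coefficients
#'
#' The per-cage and overall selection coefficients reported for the
#' mtDNA-haplotype population-cage study this pipeline re-implements
#' (2 nuclear backgrounds x melanogaster/simulans haplotype sets x
#' pre/post phases, 4 replicate cages each). Shipped as a plain-text
#' table; used as reference slopes for the balanced-design consistency
#' checks and as realistic generative parameters for simulations.
#'
#' @return data frame with columns \code{nuclear_background},
#'   \code{haplotype}, \code{phase}, \code{cage}, \code{s_cage},
#'   \code{se_cage}, \code{S_overall}, \code{se_S}, \code{ci_low},
#'   \code{ci_high}, \code{v_r} (as printed, including "<0.001"),
#'   \code{lrt_p}.
#' @export
published_cage_slopes <- function() {
  path <- system.file("extdata", "published_cage_slopes.csv",
                      package = "mitocage", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(v_r = "character"))
  df$phase <- factor(df$phase, levels = c("pre", "post"))
  df
}
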