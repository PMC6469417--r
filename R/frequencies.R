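#' Estimate haplotype-frequency trajectories from genotype counts
#'
#' Converts scored-fly counts into per-generation haplotype frequency
#' estimates with binomial standard errors. The estimate at each sampled
#' generation is \code{count / n_scored}, where \code{n_scored} is the
#' total number of flies scored in that cage-generation. Generation-0
#' frequencies are these estimates, never the seeded founder ratio: the
#' flies actually alive at the end of the starting generation define the
#' starting frequency.
#'
#' @param counts a genotype-count table ([read_genotype_counts()] or the
#'   \code{counts} element of [simulate_experiment()]).
#' @return data frame of class \code{"freq_table"}: one row per cage x
#'   phase x generation x haplotype, with \code{count}, \code{n_scored},
#'   \code{freq} and binomial standard error \code{se}
#'   (\eqn{\sqrt{p(1-p)/n}}; exactly 0 when \code{freq} is 0 or 1).
#' @export
estimate_frequencies <- function(counts) {
  counts <- validate_genotype_counts(as.data.frame(counts))
  key <- interaction(counts$cage_id, counts$phase, counts$generation, drop = TRUE)
  n_scored <- stats::ave(counts$count, key, FUN = sum)
  zero <- unique(counts[n_scored == 0L,
                        c("cage_id", "phase", "generation")])
  if (nrow(zero))
    stop(sprintf("cage-generation(s) with zero scored flies: %s",
                 paste(sprintf("%s/%s gen %d", zero$cage_id, zero$phase,
                               zero$generation), collapse = "; ")))
  out <- counts
  out$n_scored <- as.integer(n_scored)
  out$freq <- out$count / out$n_scored
  out$se <- sqrt(out$freq * (1 - out$freq) / out$n_scored)
  out <- out[order(out$cage_id, out$phase, out$generation, out$haplotype), ]
  rownames(out) <- NULL
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Write frequency trajectories to CSV
#'
#' Serializes a frequency table to the canonical comma-separated layout.
#' Numeric columns are written with 15 significant digits so a read-back
#' reproduces the values to full double precision.
#'
#' @param freq a \code{"freq_table"} from [estimate_frequencies()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_frequencies <- function(freq, path) {
  if (!is.data.frame(freq) || nrow(freq) == 0L)
    stop("no trajectories to write")
  out <- as.data.frame(freq)
  for (col in c("freq", "se"))
    out[[col]] <- format(out[[col]], digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read frequency trajectories written by [write_frequencies()]
#'
#' @param path CSV file path.
#' @return data frame of class \code{"freq_table"}.
#' @export
read_frequencies <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cage_id", "nuclear_background", "phase", "generation",
            "haplotype", "count", "n_scored", "freq", "se")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("frequency file missing column(s): %s",
                 paste(missing, collapse = ", ")))
  class(df) <- c("freq_table", "data.frame")
  df
}
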