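#' Plot mean haplotype frequencies across replicate cages
#'
#' Mean estimated frequency (+/- 1 SEM across cages) per haplotype over
#' sampled generations, one panel per phase. Advisory output: the numeric
#' tables are the tested surface.
#'
#' @param freq a \code{"freq_table"}.
#' @param main plot title.
#' @return invisibly, the data frame of plotted means and SEMs.
#' @export
plot_mean_frequencies <- function(freq, main = "Mean haplotype frequency") {
  stopifnot(is.data.frame(freq))
  agg <- stats::aggregate(freq ~ haplotype + generation + phase, data = freq,
                          FUN = function(x) c(mean = mean(x),
                                              sem = stats::sd(x) / sqrt(length(x))))
  agg <- do.call(data.frame, agg)
  names(agg)[4:5] <- c("mean", "sem")
  phases <- intersect(c("pre", "post"), unique(agg$phase))
  haps <- sort(unique(agg$haplotype))
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(haps)), "Dark 3")[seq_along(haps)],
                          haps)
  op <- graphics::par(mfrow = c(1, length(phases)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (ph in phases) {
    a <- agg[agg$phase == ph, ]
    graphics::plot(NA, xlim = range(a$generation), ylim = c(0, 1),
                   xlab = "Generation", ylab = "Frequency",
                   main = sprintf("%s (%s)", main, ph))
    for (h in haps) {
      ah <- a[a$haplotype == h, ]
      ah <- ah[order(ah$generation), ]
      graphics::lines(ah$generation, ah$mean, col = cols[h], lwd = 2)
      graphics::points(ah$generation, ah$mean, col = cols[h], pch = 16)
      graphics::arrows(ah$generation, ah$mean - ah$sem,
                       ah$generation, ah$mean + ah$sem,
                       angle = 90, code = 3, length = 0.03, col = cols[h])
    }
    graphics::legend("topleft", legend = haps, col = cols[haps], lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(agg)
}
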