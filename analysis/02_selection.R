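#!/usr/bin/env Rscript
# Selection-coefficient inference on a genotype-count table: per-cage
# log-frequency slopes, cross-cage mixed-model summaries with bootstrap
# CIs, repeatability (V_R) tests, phase comparisons and haplotype ranks.
# Writes the published-table-shaped summary CSV and a trajectory figure.
#
# Usage: Rscript analysis/02_selection.R [--counts <csv>] [--out <dir>]
#          [--seed <int>] [--draws <int>] [--zero-policy drop|continuity]

suppressPackageStartupMessages(library(mitocage))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
counts_path <- get_arg("--counts", "results/genotype_counts.csv")
out_dir <- get_arg("--out", "results")
seed <- as.integer(get_arg("--seed", "20260922"))
n_draws <- as.integer(get_arg("--draws", "5000"))
zero_policy <- get_arg("--zero-policy", "drop")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

counts <- read_genotype_counts(counts_path)
# treatment sets were labelled <treatment>_<cage>; summarize per treatment
counts$treatment <- sub("_cage[0-9]+$", "", counts$cage_id)
freq <- estimate_frequencies(counts[, setdiff(names(counts), "treatment")])
freq$treatment <- sub("_cage[0-9]+$", "", freq$cage_id)
write_frequencies(freq[, setdiff(names(freq), "treatment")],
                  file.path(out_dir, "frequencies.csv"))

tables <- list()
comparisons <- list()
for (tt in unique(freq$treatment)) {
  ft <- freq[freq$treatment == tt, ]
  haps <- sort(unique(ft$haplotype))
  focal <- if (length(haps) == 2L)
    stats::setNames("OreR", unique(ft$nuclear_background)) else NULL
  tab <- selection_summary_table(ft, n_draws = n_draws, seed = seed,
                                 zero_policy = zero_policy, focal = focal)
  tables[[tt]] <- tab
  message(sprintf("-- %s --", tt))
  report_haps <- unique(tab$haplotype)
  for (h in report_haps) {
    for (ph in c("pre", "post")) {
      row <- tab[tab$haplotype == h & tab$phase == ph, ][1, ]
      message(sprintf("  %s %-5s S = %+.4f [%+.4f, %+.4f] V_R = %.3f (p = %.3g) -> %s",
                      ph, h, row$S_haplotype, row$ci_low, row$ci_high,
                      row$V_R, row$lrt_p, row$classification))
    }
    pre <- fit_haplotype_summary(ft, h, phase = "pre", n_draws = n_draws,
                                 seed = seed + 1, zero_policy = zero_policy)
    post <- fit_haplotype_summary(ft, h, phase = "post", n_draws = n_draws,
                                  seed = seed + 2, zero_policy = zero_policy)
    cmp <- compare_phases(pre, post)
    comparisons[[paste(tt, h)]] <- data.frame(
      treatment = tt, haplotype = h,
      S_pre = pre$S, S_post = post$S,
      class_pre = pre$classification, class_post = post$classification,
      sign_agreement = cmp$sign_agreement,
      selection_agreement = cmp$selection_agreement)
  }
  rank_pre <- rank_haplotypes(ft, phase = "pre")
  rank_post <- rank_haplotypes(ft, phase = "post")
  message(sprintf("  rank (final gen): pre %s | post %s",
                  paste(rank_pre, collapse = " > "),
                  paste(rank_post, collapse = " > ")))
}

summary_tab <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
utils::write.csv(summary_tab, file.path(out_dir, "selection_summary.csv"),
                 row.names = FALSE)
cmp_tab <- do.call(rbind, c(comparisons, list(make.row.names = FALSE)))
utils::write.csv(cmp_tab, file.path(out_dir, "phase_comparisons.csv"),
                 row.names = FALSE)

dir.create(file.path(out_dir, "figures"), showWarnings = FALSE)
grDevices::pdf(file.path(out_dir, "figures", "trajectories.pdf"),
               width = 9, height = 4)
for (tt in unique(freq$treatment))
  plot_mean_frequencies(freq[freq$treatment == tt, ], main = tt)
invisible(grDevices::dev.off())
message("wrote selection_summary.csv, phase_comparisons.csv and figures/")
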