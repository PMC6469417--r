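# Build a frequency table directly from per-cage log-frequency vectors,
# bypassing the count layer (used when the test controls ln p exactly).
freq_table_from_logfreq <- function(y_by_cage, generations,
                                    haplotype = "h", phase = "pre",
                                    nuclear_background = "x") {
  rows <- lapply(names(y_by_cage), function(id) {
    data.frame(cage_id = id, nuclear_background = nuclear_background,
               phase = phase, generation = as.integer(generations),
               haplotype = haplotype, count = NA_integer_,
               n_scored = NA_integer_, freq = exp(y_by_cage[[id]]),
               se = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("freq_table", "data.frame")
  out
}

# A small valid genotype-count table: 2 cages x 3 generations x 2 haplotypes.
make_counts <- function() {
  expand <- expand.grid(haplotype = c("A", "B"), generation = c(0L, 3L, 6L),
                        cage_id = c("cage1", "cage2"),
                        stringsAsFactors = FALSE)
  expand$nuclear_background <- "OreR"
  expand$phase <- "pre"
  expand$count <- c(40L, 52L, 35L, 55L, 30L, 60L,
                    45L, 47L, 41L, 50L, 38L, 52L)
  expand[, c("cage_id", "nuclear_background", "phase", "generation",
             "haplotype", "count")]
}

# Convert simulated cage trajectories into a canonical count table.
cages_to_counts <- function(trajectories, nuclear_background = "x",
                            phase = "pre") {
  do.call(rbind, lapply(trajectories, function(tr)
    mitocage:::.counts_to_rows(tr, tr$cage_id, nuclear_background, phase)))
}

# Independent brute-force ML for the random-intercept model on a grid over
# (v, r): builds the full covariance matrix and evaluates the Gaussian
# likelihood directly. Deliberately naive; the oracle for the fast fitter.
grid_ml_oracle <- function(y, x, group, v_grid, r_grid) {
  X <- cbind(1, x)
  g <- as.integer(factor(group))
  Z <- outer(g, sort(unique(g)), "==") * 1
  best <- list(ll = -Inf)
  for (v in v_grid) for (r in r_grid) {
    V <- v * tcrossprod(Z) + r * diag(length(y))
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    e <- y - X %*% beta
    ll <- -0.5 * (length(y) * log(2 * pi) +
                    determinant(V)$modulus[1] + t(e) %*% Vi %*% e)
    if (ll > best$ll)
      best <- list(ll = as.numeric(ll), v = v, r = r,
                   slope = beta[2], intercept = beta[1])
  }
  best
}
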