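# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# summary.lm warns on zero-residual fits; exact (noiseless) trajectories
# are legitimate inputs here, so that specific warning is muffled.
.muffle_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w), fixed = TRUE))
      invokeRestart("muffleWarning")
  })
}

# Collect validation messages; stop with all of them at once.
.fail_all <- function(problems, context) {
  problems <- problems[!vapply(problems, is.null, logical(1))]
  if (length(problems))
    stop(sprintf("%s:\n%s", context,
                 paste0("  - ", unlist(problems), collapse = "\n")),
         call. = FALSE)
  invisible(TRUE)
}
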