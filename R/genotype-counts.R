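.count_cols <- c("cage_id", "nuclear_background", "phase", "generation",
                 "haplotype", "count")

#' Read a long-format genotype-count table
#'
#' Reads the canonical comma-separated genotype-count file: one row per
#' cage x generation x haplotype with the number of flies scored for that
#' haplotype. Required columns (case-insensitive): \code{cage_id},
#' \code{nuclear_background}, \code{phase} (\code{pre}/\code{post}),
#' \code{generation}, \code{haplotype}, \code{count}. A \code{control}
#' column, if present, is dropped with a warning (control wells are assumed
#' already excluded from counts). Files in other dialects can be mapped via
#' \code{col_map}, a named character vector \code{c(canonical = "file
#' column")}.
#'
#' All validation failures are collected and reported together, with the
#' offending rows named.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector renaming file columns to
#'   the canonical schema.
#' @return validated data frame of class \code{"genotype_counts"}.
#' @export
read_genotype_counts <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!is.null(col_map)) {
    m <- match(tolower(col_map), names(df))
    if (anyNA(m))
      stop(sprintf("col_map names columns absent from the file: %s",
                   paste(col_map[is.na(m)], collapse = ", ")))
    names(df)[m] <- names(col_map)
  }
  if ("control" %in% names(df)) {
    warning("dropping 'control' column: control wells must already be excluded from counts")
    df$control <- NULL
  }
  validate_genotype_counts(df)
}

#' Validate a genotype-count table
#'
#' Checks the canonical schema and content invariants: required columns
#' present, non-empty, counts non-negative integers, no duplicate
#' (cage, phase, generation, haplotype) keys, and a consistent haplotype
#' set across the generations of each cage x phase. Every violation is
#' reported, not just the first.
#'
#' @param df data frame in the canonical long format.
#' @return the table, classed \code{"genotype_counts"}, invisibly valid.
#' @export
validate_genotype_counts <- function(df) {
  problems <- list()
  missing <- setdiff(.count_cols, names(df))
  if (length(missing))
    problems <- c(problems, sprintf("missing column(s): %s",
                                    paste(missing, collapse = ", ")))
  if (!length(missing) && nrow(df) == 0L)
    problems <- c(problems, "table is empty")
  .fail_all(problems, "invalid genotype-count table")

  df <- df[.count_cols]
  df$generation <- as.integer(df$generation)
  bad_phase <- which(!df$phase %in% c("pre", "post"))
  if (length(bad_phase))
    problems <- c(problems, sprintf("phase must be 'pre' or 'post' (rows %s)",
                                    paste(bad_phase, collapse = ", ")))
  bad_count <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad_count))
    problems <- c(problems,
                  sprintf("count must be a non-negative integer (rows %s)",
                          paste(bad_count, collapse = ", ")))
  key <- paste(df$cage_id, df$phase, df$generation, df$haplotype, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    problems <- c(problems,
                  sprintf("duplicate (cage, phase, generation, haplotype) keys (rows %s)",
                          paste(dup, collapse = ", ")))
  # haplotype set must not change across a cage's generations
  for (cp in split(df, list(df$cage_id, df$phase), drop = TRUE)) {
    sets <- lapply(split(cp$haplotype, cp$generation),
                   function(h) sort(unique(h)))
    if (length(unique(vapply(sets, paste, character(1), collapse = ","))) > 1L)
      problems <- c(problems,
                    sprintf("cage %s (%s phase): haplotype set differs across generations",
                            cp$cage_id[1L], cp$phase[1L]))
  }
  .fail_all(problems, "invalid genotype-count table")
  df$count <- as.integer(df$count)
  class(df) <- c("genotype_counts", "data.frame")
  df
}

#' Write a genotype-count table to the canonical CSV
#'
#' @param counts table in the canonical long format.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_counts <- function(counts, path) {
  counts <- validate_genotype_counts(as.data.frame(counts))
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
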