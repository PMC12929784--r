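# Controlled vocabularies used across the data model. Copy-number classes are
# the only ones that may carry a numeric copy_number value.
dna_alteration_classes <- function() {
  c("frameshift_or_stopgain", "copy_number_gain", "copy_number_loss",
    "missense_snv", "fusion_or_rearrangement", "splice_site")
}

copy_number_classes <- function() c("copy_number_gain", "copy_number_loss")

rna_directions <- function() c("over", "under")

pdl1_levels <- function() c("positive", "negative", "unknown")

sex_levels <- function() c("male", "female")

# Priority used to pick one "primary" alteration class per concordant event
# when a (patient, gene) carries several DNA calls. Copy-number first: at the
# event level one class is reported per event and copy-number dominates.
default_class_priority <- function() {
  c("copy_number_gain", "copy_number_loss", "fusion_or_rearrangement",
    "splice_site", "frameshift_or_stopgain", "missense_snv")
}

#' Two-sided Mann-Whitney U comparison of two samples
#'
#' Shared rank-sum helper used by [purity_concordance_test()] and
#' [ttb_by_pdl1_test()]. Uses the exact null distribution when both groups
#' have at most `exact_max` observations and the pooled sample is tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction. Empty groups (after dropping `NA`) yield a one-row result with
#' `status = "insufficient_data"` rather than an error, so callers can report
#' degenerate cohorts gracefully.
#'
#' @param x,y Numeric vectors; `NA` values are dropped.
#' @param exact_max Largest per-group size for which the exact test is used.
#' @return A one-row tibble: `status`, `n_x`, `n_y`, `u` (the Mann-Whitney U
#'   for `x` relative to `y`), `p_value`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    return(tibble(
      status = "insufficient_data", n_x = length(x), n_y = length(y),
      u = NA_real_, p_value = NA_real_, method = NA_character_
    ))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble(
    status = "ok", n_x = length(x), n_y = length(y),
    u = unname(wt$statistic), p_value = unname(wt$p.value),
    method = if (exact) "exact" else "normal_approximation"
  )
}

# Row-addressed validation failure.
validation_error <- function(msg, rows = NULL, file = NULL) {
  loc <- NULL
  if (!is.null(rows)) {
    shown <- paste(utils::head(rows, 5), collapse = ", ")
    more <- if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5) else ""
    loc <- sprintf("rows: %s%s", shown, more)
  }
  if (!is.null(file)) loc <- paste(c(sprintf("file: %s", file), loc), collapse = "; ")
  abort(paste(c(msg, loc), collapse = " — "), class = "rnaconcord_validation_error")
}

check_required_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s.\nExpected header: %s",
      what, paste(missing, collapse = ", "), paste(required, collapse = "\t")
    ), class = "rnaconcord_validation_error")
  }
  invisible(df)
}
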