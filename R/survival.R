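ttb_stratum_labels <- function(breaks) {
  breaks <- sort(as.integer(breaks))
  if (length(breaks) == 2) return(c("low", "mid", "high"))
  lo <- c(0L, breaks + 1L)
  hi <- c(breaks, NA)
  ifelse(is.na(hi), sprintf(">=%d", lo),
         ifelse(lo == hi, sprintf("%d", lo), sprintf("%d-%d", lo, hi)))
}

#' Tumor transcriptional burden per patient
#'
#' TTB is the number of distinct genes with altered expression in a patient's
#' RNA profiling report — over- and underexpression both count, each gene
#' once. Patients with no RNA calls get a TTB of zero. Patients are binned
#' into strata by a sorted vector of inclusive upper bounds: the default
#' `c(2, 5)` gives the strata 0-2 (`low`), 3-5 (`mid`) and >=6 (`high`).
#'
#' @param x A [cohort()] object.
#' @param breaks Sorted integer vector of inclusive upper TTB bounds
#'   (default `c(2, 5)`).
#' @return Tibble with `patient_id`, `ttb` and `stratum` (ordered factor;
#'   labels `low`/`mid`/`high` for two breaks, TTB ranges otherwise).
#' @export
compute_ttb <- function(x, breaks = c(2, 5)) {
  stopifnot(inherits(x, "cohort"))
  breaks <- sort(as.integer(breaks))
  if (length(breaks) < 1 || anyNA(breaks) || any(breaks < 0)) {
    abort("`breaks` must be non-negative integers")
  }
  labels <- ttb_stratum_labels(breaks)
  altered_gene_counts(x, "rna") |>
    rename(ttb = "n_genes") |>
    mutate(stratum = cut(.data$ttb, breaks = c(-Inf, breaks, Inf),
                         labels = labels, ordered_result = TRUE))
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival with the standard tie convention (deaths precede
#' censorings at equal times) and Greenwood standard errors; computed with
#' the survival package.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1): `TRUE` when death was observed, `FALSE`
#'   when right-censored.
#' @return Tibble of class `km_curve`, one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`
#'   (Greenwood SE of the survival probability).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) abort("empty survival input")
  if (length(times) != length(events)) abort("`times` and `events` lengths differ")
  if (anyNA(times) || any(times < 0)) abort("`times` must be non-negative and complete")
  events <- as.logical(events)
  if (anyNA(events)) abort("`events` must be logical and complete")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  sm <- summary(fit, censored = TRUE)
  out <- tibble(
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    n_censor = sm$n.censor, survival = sm$surv, std_err = sm$std.err
  )
  structure(out, n = length(times), class = c("km_curve", class(out)))
}

#' Median survival from a Kaplan-Meier fit
#'
#' First time at which the product-limit estimate drops to 0.5 or below,
#' with the usual convention that a plateau at exactly 0.5 yields the
#' midpoint of its boundary times; `NA` when the curve never reaches 0.5.
#'
#' @inheritParams km_estimate
#' @return Median survival time (scalar).
#' @export
km_median <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  unname(summary(fit)$table["median"])
}

#' K-sample log-rank test
#'
#' Score test comparing survival distributions across groups via observed
#' minus expected event counts over the shared risk sets, with
#' hypergeometric variance; the statistic is referred to a chi-squared
#' distribution on (number of non-empty groups - 1) degrees of freedom.
#' Computed with `survival::survdiff()`.
#'
#' @param times,events As in [km_estimate()].
#' @param group Group labels (factor or character), same length.
#' @return One-row tibble of class `logrank_result`: `statistic`, `df`,
#'   `p_value`, `n_groups`.
#' @export
logrank_test <- function(times, events, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) abort("log-rank test needs at least 2 non-empty groups")
  if (length(unique(c(length(times), length(events), length(group)))) != 1) {
    abort("`times`, `events` and `group` lengths differ")
  }
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ group)
  df <- nlevels(group) - 1L
  out <- tibble(
    statistic = unname(sd$chisq), df = df,
    p_value = stats::pchisq(unname(sd$chisq), df = df, lower.tail = FALSE),
    n_groups = nlevels(group)
  )
  structure(out, class = c("logrank_result", class(out)))
}

#' Overall survival stratified by tumor transcriptional burden
#'
#' The TTB survival analysis: computes per-patient TTB, assigns strata,
#' restricts to treated patients by default (the survival question concerns
#' patients who went on to receive therapy), fits a Kaplan-Meier curve per
#' stratum and compares strata with the log-rank test. Strata left empty
#' after restriction are dropped from the comparison.
#'
#' @param x A [cohort()] object.
#' @param breaks TTB stratum bounds, as in [compute_ttb()].
#' @param treated_only Restrict to `treated == TRUE` patients (default).
#' @return Object of class `ttb_survival`: list with `records` (patient_id,
#'   ttb, stratum, os_months, os_event), `curves` (per-stratum KM
#'   coordinates), `medians` (per-stratum n, events and median OS), and
#'   `logrank` (a [logrank_test()] result, or `NULL` with fewer than 2
#'   non-empty strata).
#' @export
ttb_survival <- function(x, breaks = c(2, 5), treated_only = TRUE) {
  stopifnot(inherits(x, "cohort"))
  records <- compute_ttb(x, breaks) |>
    inner_join(select(x$patients, "patient_id", "treated", "os_months", "os_event"),
               by = "patient_id")
  if (treated_only) records <- filter(records, .data$treated)
  records <- select(records, -"treated")
  if (!nrow(records)) abort("no patients left for survival analysis")

  by_stratum <- split(records, records$stratum, drop = TRUE)
  curves <- bind_rows(lapply(names(by_stratum), function(s) {
    km <- km_estimate(by_stratum[[s]]$os_months, by_stratum[[s]]$os_event)
    mutate(as_tibble(km), stratum = s, .before = 1)
  }))
  medians <- bind_rows(lapply(names(by_stratum), function(s) {
    d <- by_stratum[[s]]
    tibble(stratum = s, n = nrow(d), n_events = sum(d$os_event),
           median_os = km_median(d$os_months, d$os_event))
  }))
  lr <- if (length(by_stratum) >= 2) {
    logrank_test(records$os_months, records$os_event, records$stratum)
  } else NULL
  structure(list(records = records, curves = curves, medians = medians,
                 logrank = lr, breaks = sort(as.integer(breaks)),
                 treated_only = treated_only),
            class = "ttb_survival")
}

#' @export
print.ttb_survival <- function(x, ...) {
  cat(sprintf("<ttb_survival> %d patients%s, strata by TTB breaks {%s}\n",
              nrow(x$records), if (x$treated_only) " (treated only)" else "",
              paste(x$breaks, collapse = ", ")))
  for (i in seq_len(nrow(x$medians))) {
    cat(sprintf("  %s: n=%d, events=%d, median OS %s months\n",
                x$medians$stratum[i], x$medians$n[i], x$medians$n_events[i],
                format(round(x$medians$median_os[i], 1))))
  }
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chi-squared %.2f on %d df, p = %.3g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  }
  invisible(x)
}

#' @rdname ttb_survival
#' @param ... Unused.
#' @export
tidy.ttb_survival <- function(x, ...) x$curves

#' @rdname ttb_survival
#' @export
glance.ttb_survival <- function(x, ...) {
  out <- tibble(
    n = nrow(x$records),
    n_strata = nrow(x$medians),
    logrank_statistic = if (is.null(x$logrank)) NA_real_ else x$logrank$statistic,
    logrank_df = if (is.null(x$logrank)) NA_integer_ else x$logrank$df,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p_value
  )
  med <- setNames(x$medians$median_os, paste0("median_os_", x$medians$stratum))
  dplyr::bind_cols(out, as_tibble(as.list(med)))
}

#' TTB by PD-L1 status
#'
#' Two-sided Mann-Whitney comparison of tumor transcriptional burden between
#' PD-L1-negative and PD-L1-positive patients; patients with unknown PD-L1
#' status are excluded from this comparison only. TTB is heavily tied, so
#' the tie-corrected normal approximation is used except in tiny tie-free
#' groups.
#'
#' @param x A [cohort()] object.
#' @param ttb Optionally a precomputed [compute_ttb()] table.
#' @return One-row tibble as from [mann_whitney_test()] (with `x` = the
#'   PD-L1-negative group), plus group medians.
#' @export
ttb_by_pdl1_test <- function(x, ttb = NULL) {
  stopifnot(inherits(x, "cohort"))
  ttb <- ttb %||% compute_ttb(x)
  d <- inner_join(ttb, select(x$patients, "patient_id", "pdl1_status"),
                  by = "patient_id") |>
    filter(.data$pdl1_status %in% c("positive", "negative"))
  res <- mann_whitney_test(d$ttb[d$pdl1_status == "negative"],
                           d$ttb[d$pdl1_status == "positive"])
  mutate(res,
         median_ttb_negative = stats::median(d$ttb[d$pdl1_status == "negative"]),
         median_ttb_positive = stats::median(d$ttb[d$pdl1_status == "positive"]))
}

#' Pearson chi-squared test for a 2x2 baseline-characteristics table
#'
#' Compares a binary characteristic between two patient groups, as in a
#' Table-1-style comparison of profiled vs not-profiled patients. The Yates
#' continuity correction (|O - E| reduced by 0.5, floored at 0) is applied
#' by default.
#'
#' @param counts A 2x2 matrix (groups in rows, characteristic levels in
#'   columns) or a length-4 vector `c(a, b, c, d)` filling the matrix by row:
#'   `rbind(c(a, b), c(c, d))`.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `yates`.
#' @examples
#' # age >= 60: 126/253 profiled vs 80/185 not
#' baseline_chi2(rbind(c(126, 127), c(80, 105)))
#' @export
baseline_chi2 <- function(counts, yates = TRUE) {
  if (!is.matrix(counts)) {
    if (length(counts) != 4) abort("`counts` must be a 2x2 matrix or length-4 vector")
    counts <- matrix(counts, nrow = 2, byrow = TRUE)
  }
  if (!all(dim(counts) == 2)) abort("`counts` must be 2x2")
  if (anyNA(counts) || any(counts < 0)) abort("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value), yates = yates)
}

#' Write survival tables
#'
#' `write_survival()` writes the per-patient TTB/OS records;
#' `write_km_curves()` writes the per-stratum Kaplan-Meier coordinates.
#'
#' @param x A `ttb_survival` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_survival <- function(x, path) {
  stopifnot(inherits(x, "ttb_survival"))
  readr::write_tsv(x$records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_survival
#' @export
write_km_curves <- function(x, path) {
  stopifnot(inherits(x, "ttb_survival"))
  readr::write_tsv(x$curves, path, na = "NA", progress = FALSE)
  invisible(path)
}
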