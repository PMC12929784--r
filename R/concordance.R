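#' Detect same-gene DNA/RNA concordant events
#'
#' A concordant event is a (patient, gene) pair reported as altered by both
#' DNA profiling and RNA profiling, regardless of alteration class or
#' expression direction (a deletion with overexpression still counts; class
#' composition is tabulated separately by [event_class_breakdown()]). When a
#' (patient, gene) carries several DNA calls, one primary class is assigned
#' by priority — copy-number first, then fusion/rearrangement, splice site,
#' frameshift/stop-gain, missense — and the copy-number value, if any, is
#' taken from the prioritised copy-number call.
#'
#' @param x A [cohort()] object.
#' @param class_priority Character vector ordering the DNA alteration classes
#'   from highest to lowest priority for primary-class assignment.
#' @return An object of class `concordance_summary`: list with
#'   * `events`: tibble with one row per event (`patient_id`, `gene`,
#'     `dna_classes` collapsed with `";"`, `primary_class`, `rna_direction`,
#'     `copy_number`, `expression_score`);
#'   * `per_patient_event_counts`: tibble `patient_id`, `n_events` for
#'     patients with at least one event;
#'   * `genes_involved`: character vector of event genes.
#' @export
detect_concordant_events <- function(x, class_priority = default_class_priority()) {
  stopifnot(inherits(x, "cohort"))
  if (!setequal(class_priority, dna_alteration_classes())) {
    abort("`class_priority` must be a permutation of the DNA alteration classes")
  }
  dna <- x$dna_calls |>
    mutate(.prio = match(.data$alteration_class, class_priority)) |>
    group_by(.data$patient_id, .data$gene) |>
    summarise(
      dna_classes = paste(sort(unique(.data$alteration_class)), collapse = ";"),
      primary_class = .data$alteration_class[which.min(.data$.prio)],
      copy_number = .data$copy_number[which.min(.data$.prio)],
      .groups = "drop"
    )
  events <- inner_join(
    dna,
    select(x$rna_calls, "patient_id", "gene",
           rna_direction = "direction", "expression_score"),
    by = c("patient_id", "gene")
  ) |>
    arrange(.data$patient_id, .data$gene)
  structure(list(
    events = events,
    per_patient_event_counts = count(events, .data$patient_id, name = "n_events"),
    genes_involved = sort(unique(events$gene))
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d events in %d patients, %d genes\n",
              nrow(x$events), nrow(x$per_patient_event_counts),
              length(x$genes_involved)))
  invisible(x)
}

#' @rdname detect_concordant_events
#' @param ... Unused.
#' @export
tidy.concordance_summary <- function(x, ...) x$events

#' @rdname detect_concordant_events
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_patients_with_events = nrow(x$per_patient_event_counts),
    n_genes_involved = length(x$genes_involved)
  )
}

#' Totals implied by an events-per-patient distribution
#'
#' Given a histogram mapping events-per-patient to number of patients,
#' returns the implied totals: patients is the sum of the counts and events
#' the count-weighted sum of the keys. Useful for checking the internal
#' consistency of reported event distributions.
#'
#' @param distribution Either a named numeric vector (names = events per
#'   patient) or a data frame with columns `events_per_patient` and
#'   `n_patients`.
#' @return A one-row tibble with `n_patients` and `n_events`.
#' @examples
#' events_from_distribution(c(`1` = 44, `2` = 4, `3` = 2))
#' @export
events_from_distribution <- function(distribution) {
  if (is.data.frame(distribution)) {
    check_required_columns(distribution, c("events_per_patient", "n_patients"),
                           "distribution table")
    k <- distribution$events_per_patient
    cnt <- distribution$n_patients
  } else {
    if (length(distribution) && is.null(names(distribution))) {
      abort("`distribution` vector must be named by events-per-patient")
    }
    k <- as.numeric(names(distribution))
    cnt <- as.numeric(distribution)
  }
  if (anyNA(k) || anyNA(cnt)) abort("`distribution` contains non-numeric entries")
  if (any(k < 0) || any(cnt < 0) || any(k != floor(k)) || any(cnt != floor(cnt))) {
    abort("`distribution` keys and counts must be non-negative integers")
  }
  tibble(n_patients = sum(cnt), n_events = sum(k * cnt))
}

#' Breakdown of concordant events by primary alteration class
#'
#' @param x A `concordance_summary` from [detect_concordant_events()].
#' @return Tibble with `primary_class`, `n` and `pct`; counts sum to the
#'   total number of events, percentages to 100 within rounding. Copy-number
#'   gain and loss are reported separately; use
#'   `dplyr::mutate(grp = sub("copy_number_.*", "copy_number", primary_class))`
#'   to pool them.
#' @export
event_class_breakdown <- function(x) {
  stopifnot(inherits(x, "concordance_summary"))
  out <- count(x$events, .data$primary_class, sort = TRUE)
  mutate(out, pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else numeric(0))
}

#' Spearman correlation of copy number and expression among concordant events
#'
#' Uses the events that carry both a numeric copy-number value (from the DNA
#' call) and an expression score (from the RNA call); ties get midranks.
#' Fewer than three usable events yields an `insufficient_data` result rather
#' than an error.
#'
#' @param x A `concordance_summary`.
#' @return One-row tibble: `status`, `n_events_used`, `spearman_rho`.
#' @export
cn_expression_correlation <- function(x) {
  stopifnot(inherits(x, "concordance_summary"))
  ev <- filter(x$events, !is.na(.data$copy_number), !is.na(.data$expression_score))
  if (nrow(ev) < 3) {
    return(tibble(status = "insufficient_data", n_events_used = nrow(ev),
                  spearman_rho = NA_real_))
  }
  tibble(
    status = "ok", n_events_used = nrow(ev),
    spearman_rho = stats::cor(ev$copy_number, ev$expression_score,
                              method = "spearman")
  )
}

#' Tumor purity in patients with vs without concordant events
#'
#' Two-sided Mann-Whitney comparison of tumor purity between patients showing
#' at least one concordant event and those showing none; patients with
#' missing purity are excluded. Higher purity in the concordant group is the
#' expected pattern, since low tumor content masks same-gene signals.
#'
#' @param x A [cohort()] object.
#' @param summary Optionally, a precomputed `concordance_summary`; detected
#'   from `x` when `NULL`.
#' @return One-row tibble as returned by [mann_whitney_test()], where `x` is
#'   the concordant group, plus group medians.
#' @export
purity_concordance_test <- function(x, summary = NULL) {
  stopifnot(inherits(x, "cohort"))
  summary <- summary %||% detect_concordant_events(x)
  with_event <- summary$per_patient_event_counts$patient_id
  purity <- x$patients |>
    mutate(concordant = .data$patient_id %in% with_event) |>
    filter(!is.na(.data$tumor_purity))
  res <- mann_whitney_test(purity$tumor_purity[purity$concordant],
                           purity$tumor_purity[!purity$concordant])
  mutate(res,
         median_concordant = stats::median(purity$tumor_purity[purity$concordant]),
         median_non_concordant = stats::median(purity$tumor_purity[!purity$concordant]))
}

#' Write concordant events to a TSV file
#'
#' @param x A `concordance_summary`.
#' @param path Output path (`events.tsv`).
#' @return Invisibly, `path`.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "concordance_summary"))
  readr::write_tsv(
    select(x$events, "patient_id", "gene", "primary_class", "rna_direction",
           "copy_number", "expression_score"),
    path, na = "NA", progress = FALSE)
  invisible(path)
}
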