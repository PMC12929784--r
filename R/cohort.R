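#' Normalize gene symbols
#'
#' Gene identity throughout the package is exact match on the normalized
#' symbol: whitespace-stripped and upper-cased. This is what makes "same gene"
#' well defined when intersecting DNA-report and RNA-report gene lists. No
#' alias resolution is attempted by default; an optional user-supplied alias
#' map (named character vector, `alias = canonical`, applied after case
#' normalization of both sides) is accepted for panels that use synonyms.
#'
#' @param raw Character vector of raw gene symbols.
#' @param alias_map Optional named character vector mapping alias symbols to
#'   canonical symbols.
#' @return Character vector of normalized symbols, same length as `raw`.
#' @examples
#' normalize_gene_symbol(c("tp53", " VEGFA ", "CDKN2A"))
#' @export
normalize_gene_symbol <- function(raw, alias_map = NULL) {
  out <- toupper(trimws(as.character(raw)))
  bad <- which(is.na(out) | out == "")
  if (length(bad)) {
    validation_error("empty or missing gene symbol", rows = bad)
  }
  if (!is.null(alias_map)) {
    if (is.null(names(alias_map)) || any(names(alias_map) == "")) {
      abort("`alias_map` must be a fully named character vector (alias = canonical)")
    }
    am <- setNames(toupper(trimws(unname(alias_map))), toupper(trimws(names(alias_map))))
    hit <- out %in% names(am)
    out[hit] <- unname(am[out[hit]])
  }
  out
}

patients_columns <- function() {
  c("patient_id", "tumor_type", "age_years", "sex", "n_prior_therapies",
    "ecog", "n_metastatic_sites", "albumin_low", "ldh_high", "tumor_purity",
    "pdl1_status", "treated", "os_months", "os_event")
}
dna_columns <- function() c("patient_id", "gene", "alteration_class", "copy_number")
rna_columns <- function() c("patient_id", "gene", "direction", "expression_score")

#' Assemble and validate a paired DNA/RNA profiling cohort
#'
#' A cohort is the pipeline's single input object: a patient table plus
#' call-level DNA and RNA alteration tables keyed by `patient_id`. The
#' constructor normalizes gene symbols, enforces referential integrity and
#' the controlled vocabularies, deduplicates DNA calls on
#' (patient, gene, alteration class) and collapses duplicate RNA rows for the
#' same (patient, gene) to the first occurrence with a warning.
#'
#' @param patients Data frame with columns `patient_id`, `tumor_type`,
#'   `age_years`, `sex`, `n_prior_therapies`, `ecog`, `n_metastatic_sites`,
#'   `albumin_low`, `ldh_high`, `tumor_purity`, `pdl1_status`, `treated`,
#'   `os_months`, `os_event`. `ldh_high`, `tumor_purity` and `pdl1_status`
#'   may be missing (`NA`); missing `pdl1_status` is recoded to `"unknown"`.
#' @param dna_calls Data frame with columns `patient_id`, `gene`,
#'   `alteration_class` (one of `frameshift_or_stopgain`, `copy_number_gain`,
#'   `copy_number_loss`, `missense_snv`, `fusion_or_rearrangement`,
#'   `splice_site`) and `copy_number` (numeric, only for the copy-number
#'   classes).
#' @param rna_calls Data frame with columns `patient_id`, `gene`, `direction`
#'   (`over` or `under`) and optional numeric `expression_score`.
#' @param alias_map Optional alias map passed to [normalize_gene_symbol()].
#' @return An object of class `cohort`: a list of the three validated tibbles.
#' @seealso [read_cohort()], [write_cohort()], [cohort_summary()]
#' @export
cohort <- function(patients, dna_calls = NULL, rna_calls = NULL, alias_map = NULL) {
  patients <- as_tibble(patients)
  dna_calls <- as_tibble(dna_calls %||% tibble(
    patient_id = character(), gene = character(),
    alteration_class = character(), copy_number = numeric()
  ))
  rna_calls <- as_tibble(rna_calls %||% tibble(
    patient_id = character(), gene = character(),
    direction = character(), expression_score = numeric()
  ))
  if (!"copy_number" %in% names(dna_calls)) dna_calls$copy_number <- NA_real_
  if (!"expression_score" %in% names(rna_calls)) rna_calls$expression_score <- NA_real_

  check_required_columns(patients, patients_columns(), "patients table")
  check_required_columns(dna_calls, dna_columns(), "dna_calls table")
  check_required_columns(rna_calls, rna_columns(), "rna_calls table")

  patients <- validate_patients(patients)
  dna_calls <- validate_dna_calls(dna_calls, patients$patient_id, alias_map)
  rna_calls <- validate_rna_calls(rna_calls, patients$patient_id, alias_map)

  structure(
    list(patients = patients, dna_calls = dna_calls, rna_calls = rna_calls),
    class = "cohort"
  )
}

validate_patients <- function(patients) {
  if (anyNA(patients$patient_id) || any(trimws(patients$patient_id) == "")) {
    validation_error("missing patient_id",
                     rows = which(is.na(patients$patient_id) | trimws(patients$patient_id) == ""))
  }
  dup <- which(duplicated(patients$patient_id))
  if (length(dup)) validation_error("duplicate patient_id", rows = dup)

  num_nonneg <- c("age_years", "n_prior_therapies", "n_metastatic_sites", "os_months")
  for (col in num_nonneg) {
    v <- patients[[col]]
    if (!is.numeric(v)) validation_error(sprintf("column %s must be numeric", col))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) validation_error(sprintf("negative or missing %s", col), rows = bad)
  }
  bad <- which(!patients$ecog %in% c(0L, 1L))
  if (length(bad)) validation_error("ecog must be 0 or 1", rows = bad)
  bad <- which(!patients$sex %in% sex_levels())
  if (length(bad)) validation_error("sex must be one of male, female", rows = bad)

  pp <- patients$tumor_purity
  bad <- which(!is.na(pp) & (pp < 0 | pp > 1))
  if (length(bad)) validation_error("tumor_purity must lie in [0, 1]", rows = bad)

  pd <- patients$pdl1_status
  pd[is.na(pd)] <- "unknown"
  bad <- which(!pd %in% pdl1_levels())
  if (length(bad)) validation_error("pdl1_status must be positive, negative or unknown", rows = bad)
  patients$pdl1_status <- pd

  for (col in c("albumin_low", "treated", "os_event")) {
    v <- patients[[col]]
    if (!is.logical(v)) validation_error(sprintf("column %s must be logical", col))
    bad <- which(is.na(v))
    if (length(bad)) validation_error(sprintf("missing %s", col), rows = bad)
  }
  if (!is.logical(patients$ldh_high)) {
    validation_error("column ldh_high must be logical (NA allowed)")
  }
  patients
}

validate_dna_calls <- function(dna_calls, patient_ids, alias_map = NULL) {
  orphan <- setdiff(unique(dna_calls$patient_id), patient_ids)
  if (length(orphan)) {
    abort(sprintf("dna_calls reference unknown patient_id(s): %s",
                  paste(utils::head(orphan, 5), collapse = ", ")),
          class = "rnaconcord_validation_error")
  }
  if (nrow(dna_calls)) {
    dna_calls$gene <- normalize_gene_symbol(dna_calls$gene, alias_map)
  }
  bad <- which(!dna_calls$alteration_class %in% dna_alteration_classes())
  if (length(bad)) {
    validation_error(
      sprintf("unknown alteration_class (expected one of: %s)",
              paste(dna_alteration_classes(), collapse = ", ")), rows = bad)
  }
  is_cn <- dna_calls$alteration_class %in% copy_number_classes()
  bad <- which(!is_cn & !is.na(dna_calls$copy_number))
  if (length(bad)) {
    validation_error("copy_number given for a non-copy-number alteration_class", rows = bad)
  }
  bad <- which(!is.na(dna_calls$copy_number) & dna_calls$copy_number < 0)
  if (length(bad)) validation_error("negative copy_number", rows = bad)
  distinct(dna_calls, .data$patient_id, .data$gene, .data$alteration_class,
           .keep_all = TRUE)
}

validate_rna_calls <- function(rna_calls, patient_ids, alias_map = NULL) {
  orphan <- setdiff(unique(rna_calls$patient_id), patient_ids)
  if (length(orphan)) {
    abort(sprintf("rna_calls reference unknown patient_id(s): %s",
                  paste(utils::head(orphan, 5), collapse = ", ")),
          class = "rnaconcord_validation_error")
  }
  if (nrow(rna_calls)) {
    rna_calls$gene <- normalize_gene_symbol(rna_calls$gene, alias_map)
  }
  bad <- which(!rna_calls$direction %in% rna_directions())
  if (length(bad)) validation_error("direction must be 'over' or 'under'", rows = bad)
  dup <- duplicated(rna_calls[c("patient_id", "gene")])
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate RNA call(s) for the same (patient, gene); kept first occurrence",
                 sum(dup)))
    rna_calls <- rna_calls[!dup, , drop = FALSE]
  }
  rna_calls
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d patients, %d DNA calls (%d genes), %d RNA calls (%d genes)\n",
    nrow(x$patients), nrow(x$dna_calls), dplyr::n_distinct(x$dna_calls$gene),
    nrow(x$rna_calls), dplyr::n_distinct(x$rna_calls$gene)
  ))
  invisible(x)
}

cohort_col_types <- function() {
  list(
    patients = readr::cols(
      patient_id = "c", tumor_type = "c", age_years = "d", sex = "c",
      n_prior_therapies = "d", ecog = "i", n_metastatic_sites = "d",
      albumin_low = "l", ldh_high = "l", tumor_purity = "d",
      pdl1_status = "c", treated = "l", os_months = "d", os_event = "l"
    ),
    dna = readr::cols(patient_id = "c", gene = "c", alteration_class = "c",
                      copy_number = "d"),
    rna = readr::cols(patient_id = "c", gene = "c", direction = "c",
                      expression_score = "d")
  )
}

read_tsv_checked <- function(path, col_types, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "rnaconcord_validation_error")
  }
  hdr <- names(readr::read_tsv(path, n_max = 0, progress = FALSE,
                               col_types = readr::cols(.default = "c")))
  check_required_columns(stats::setNames(as.list(hdr), hdr), required,
                         sprintf("%s (%s)", what, path))
  df <- readr::read_tsv(path, col_types = col_types, na = c("", "NA"),
                        progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("unparsable value(s) in %s (first at line %d, column %s)",
                  path, prob$row[1] + 1L, prob$col[1]),
          class = "rnaconcord_validation_error")
  }
  df
}

#' Read a cohort from three tab-delimited files
#'
#' Files are UTF-8, tab-delimited, with a mandatory header row; missing values
#' are empty fields or `NA`. See [cohort()] for the expected columns and the
#' validation performed.
#'
#' @param patients_path,dna_path,rna_path Paths to `patients.tsv`,
#'   `dna_calls.tsv` and `rna_calls.tsv`.
#' @param alias_map Optional alias map passed to [normalize_gene_symbol()].
#' @return A validated [cohort()] object.
#' @export
read_cohort <- function(patients_path, dna_path, rna_path, alias_map = NULL) {
  ct <- cohort_col_types()
  patients <- read_tsv_checked(patients_path, ct$patients, patients_columns(), "patients table")
  dna <- read_tsv_checked(dna_path, ct$dna, dna_columns(), "dna_calls table")
  rna <- read_tsv_checked(rna_path, ct$rna, rna_columns(), "rna_calls table")
  cohort(patients, dna, rna, alias_map = alias_map)
}

#' Write a cohort to tab-delimited files
#'
#' Inverse of [read_cohort()]: writes `patients.tsv`, `dna_calls.tsv` and
#' `rna_calls.tsv` into `dir`. Reading the files back yields a cohort equal
#' record-for-record to the input.
#'
#' @param x A [cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    patients = file.path(dir, "patients.tsv"),
    dna_calls = file.path(dir, "dna_calls.tsv"),
    rna_calls = file.path(dir, "rna_calls.tsv")
  )
  readr::write_tsv(x$patients, paths[["patients"]], na = "NA", progress = FALSE)
  readr::write_tsv(x$dna_calls, paths[["dna_calls"]], na = "NA", progress = FALSE)
  readr::write_tsv(x$rna_calls, paths[["rna_calls"]], na = "NA", progress = FALSE)
  invisible(paths)
}

#' Per-patient distinct altered-gene counts
#'
#' Counts genes, not call records: a gene with both an amplification and a
#' missense call in the same patient counts once. Every patient appears,
#' including those with zero calls.
#'
#' @param x A [cohort()] object.
#' @param assay `"dna"` or `"rna"`.
#' @return Tibble with `patient_id` and `n_genes`.
#' @export
altered_gene_counts <- function(x, assay = c("dna", "rna")) {
  assay <- match.arg(assay)
  calls <- if (assay == "dna") x$dna_calls else x$rna_calls
  counts <- calls |>
    distinct(.data$patient_id, .data$gene) |>
    count(.data$patient_id, name = "n_genes")
  tibble(patient_id = x$patients$patient_id) |>
    left_join(counts, by = "patient_id") |>
    mutate(n_genes = tidyr::replace_na(.data$n_genes, 0L))
}

#' Summarise a cohort
#'
#' Computes the descriptive summaries reported for a paired-profiling cohort:
#' unique altered genes per assay, the per-patient distribution of distinct
#' altered genes (median and range), and the alteration-class / expression-
#' direction mixtures over call records.
#'
#' @param x A [cohort()] object.
#' @return An object of class `cohort_summary`: a list with `n_patients`,
#'   `n_dna_genes`, `n_rna_genes`, `per_patient` (one row per assay with
#'   median/min/max of distinct altered genes), `class_mixture` and
#'   `direction_mixture` tibbles (counts and percentages over call records).
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  dna_counts <- altered_gene_counts(x, "dna")
  rna_counts <- altered_gene_counts(x, "rna")
  dist_row <- function(assay, v) {
    if (!length(v)) v <- 0L
    tibble(assay = assay, median = stats::median(v),
           min = min(v), max = max(v))
  }
  mixture <- function(v, levels) {
    out <- tibble(value = factor(v, levels = levels)) |>
      count(.data$value, .drop = FALSE) |>
      mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)
    names(out)[1] <- "class"
    out
  }
  structure(list(
    n_patients = nrow(x$patients),
    n_dna_genes = dplyr::n_distinct(x$dna_calls$gene),
    n_rna_genes = dplyr::n_distinct(x$rna_calls$gene),
    per_patient = bind_rows(
      dist_row("dna", dna_counts$n_genes),
      dist_row("rna", rna_counts$n_genes)
    ),
    class_mixture = mixture(x$dna_calls$alteration_class, dna_alteration_classes()),
    direction_mixture = mixture(x$rna_calls$direction, rna_directions())
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients\n", x$n_patients))
  cat(sprintf("  unique altered genes: DNA %d, RNA %d\n", x$n_dna_genes, x$n_rna_genes))
  pp <- x$per_patient
  for (i in seq_len(nrow(pp))) {
    cat(sprintf("  %s genes/patient: median %g (range %g-%g)\n",
                toupper(pp$assay[i]), pp$median[i], pp$min[i], pp$max[i]))
  }
  cm <- dplyr::filter(x$class_mixture, .data$n > 0)
  if (nrow(cm)) {
    cat("  DNA call classes: ",
        paste(sprintf("%s %.1f%%", cm$class, cm$pct), collapse = ", "), "\n", sep = "")
  }
  dm <- dplyr::filter(x$direction_mixture, .data$n > 0)
  if (nrow(dm)) {
    cat("  RNA directions: ",
        paste(sprintf("%s %.1f%%", dm$class, dm$pct), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname cohort_summary
#' @param x A `cohort_summary` object.
#' @param ... Unused.
#' @export
glance.cohort_summary <- function(x, ...) {
  pp <- x$per_patient
  tibble(
    n_patients = x$n_patients,
    n_dna_genes = x$n_dna_genes,
    n_rna_genes = x$n_rna_genes,
    median_dna_genes = pp$median[pp$assay == "dna"],
    max_dna_genes = pp$max[pp$assay == "dna"],
    median_rna_genes = pp$median[pp$assay == "rna"],
    max_rna_genes = pp$max[pp$assay == "rna"]
  )
}
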