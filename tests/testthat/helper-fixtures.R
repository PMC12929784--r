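# Programmatic fixtures: no data files, everything built in code.

make_patients <- function(ids, ...) {
  n <- length(ids)
  defaults <- tibble::tibble(
    patient_id = ids,
    tumor_type = "colorectal",
    age_years = 60,
    sex = rep_len(c("female", "male"), n),
    n_prior_therapies = 4,
    ecog = 1L,
    n_metastatic_sites = 2,
    albumin_low = FALSE,
    ldh_high = FALSE,
    tumor_purity = 0.6,
    pdl1_status = "negative",
    treated = TRUE,
    os_months = 12,
    os_event = TRUE
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

dna_row <- function(patient_id, gene, class = "missense_snv", copy_number = NA_real_) {
  tibble::tibble(patient_id = patient_id, gene = gene,
                 alteration_class = class, copy_number = copy_number)
}

rna_row <- function(patient_id, gene, direction = "over", score = NA_real_) {
  tibble::tibble(patient_id = patient_id, gene = gene,
                 direction = direction, expression_score = score)
}

# Three patients, five DNA calls, two RNA calls; P1 carries the only
# same-gene (KRAS) concordance.
make_toy_cohort <- function() {
  cohort(
    make_patients(c("P1", "P2", "P3")),
    dplyr::bind_rows(
      dna_row("P1", "TP53"),
      dna_row("P1", "KRAS", "copy_number_gain", 6),
      dna_row("P2", "KRAS"),
      dna_row("P2", "APC", "frameshift_or_stopgain"),
      dna_row("P3", "CDKN2A", "copy_number_loss", 0.4)
    ),
    dplyr::bind_rows(
      rna_row("P1", "KRAS", "over", 90),
      rna_row("P1", "VEGFA", "over", 80)
    )
  )
}

# Random small cohort for property-style checks; gene pools kept tiny so
# same-gene overlaps actually occur.
make_random_cohort <- function(n_patients = 12, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("R%02d", seq_len(n_patients))
    genes <- c("TP53", "KRAS", "VEGFA", "MYC", "EGFR", "CDKN2A", "AR", "ESR1")
    dna <- dplyr::bind_rows(lapply(ids, function(pid) {
      k <- sample(0:4, 1)
      if (k == 0) return(NULL)
      dna_row(pid, sample(genes, k),
              class = sample(dna_alteration_classes()[-(2:3)], k, replace = TRUE))
    }))
    rna <- dplyr::bind_rows(lapply(ids, function(pid) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      rna_row(pid, sample(genes, k),
              direction = sample(c("over", "under"), k, replace = TRUE),
              score = runif(k, 0, 100))
    }))
    cohort(make_patients(ids), dna, rna)
  })
}

write_gmt_fixture <- function(path, sets) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

write_trrust_fixture <- function(path, edges) {
  # edges: data.frame tf/target/mode
  writeLines(sprintf("%s\t%s\t%s\t12345", edges$tf, edges$target, edges$mode), path)
  path
}
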