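test_that("concordant events are exactly the same-gene intersections", {
  co <- make_toy_cohort()
  conc <- detect_concordant_events(co)
  expect_identical(nrow(conc$events), 1L)
  expect_identical(conc$events$patient_id, "P1")
  expect_identical(conc$events$gene, "KRAS")
  expect_identical(conc$events$primary_class, "copy_number_gain")
  expect_identical(conc$events$rna_direction, "over")

  # disjoint gene sets: zero events
  co2 <- cohort(make_patients("P1"), dna_row("P1", "TP53"), rna_row("P1", "MYC"))
  expect_identical(nrow(detect_concordant_events(co2)$events), 0L)
})

test_that("direction does not gate concordance and primary class follows priority", {
  # deletion with overexpression still counts as an event
  co <- cohort(make_patients("P1"),
               dplyr::bind_rows(dna_row("P1", "CDKN2A", "copy_number_loss", 0.2),
                                dna_row("P1", "CDKN2A", "missense_snv")),
               rna_row("P1", "CDKN2A", "over", 95))
  ev <- detect_concordant_events(co)$events
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$primary_class, "copy_number_loss")
  expect_identical(ev$dna_classes, "copy_number_loss;missense_snv")
  expect_identical(ev$copy_number, 0.2)

  # a custom priority reverses the choice
  prio <- rev(c("copy_number_gain", "copy_number_loss",
                "fusion_or_rearrangement", "splice_site",
                "frameshift_or_stopgain", "missense_snv"))
  ev2 <- detect_concordant_events(co, class_priority = prio)$events
  expect_identical(ev2$primary_class, "missense_snv")
})

test_that("event detection matches the brute-force nested-loop oracle", {
  for (seed in c(7, 11, 23)) {
    co <- make_random_cohort(n_patients = 15, seed = seed)
    got <- detect_concordant_events(co)$events[, c("patient_id", "gene")]
    want <- oracle_concordant_events(co)
    got <- got[order(got$patient_id, got$gene), ]
    want <- want[order(want$patient_id, want$gene), ]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
  # synthetic cohort at study scale
  co <- generate_cohort(simulation_config(n_patients = 40), seed = 7)
  got <- detect_concordant_events(co)$events
  want <- oracle_concordant_events(co)
  expect_identical(nrow(got), nrow(want))
  expect_identical(paste(got$patient_id, got$gene),
                   paste(want$patient_id, want$gene))
})

test_that("event totals follow from the events-per-patient distribution", {
  expect_equal(events_from_distribution(c(`1` = 44, `2` = 4, `3` = 2)),
               tibble::tibble(n_patients = 50, n_events = 58))
  expect_equal(events_from_distribution(numeric()),
               tibble::tibble(n_patients = 0, n_events = 0))
  expect_equal(events_from_distribution(c(`2` = 3)),
               tibble::tibble(n_patients = 3, n_events = 6))
  expect_error(events_from_distribution(c(`-1` = 3)), "non-negative")
  expect_error(events_from_distribution(c(`2` = -3)), "non-negative")
  # data-frame form
  expect_equal(
    events_from_distribution(data.frame(events_per_patient = c(1, 3),
                                        n_patients = c(2, 2))),
    tibble::tibble(n_patients = 4, n_events = 8))
})

test_that("per-patient histogram reproduces the summary totals (self-consistency)", {
  for (seed in c(3, 9)) {
    co <- make_random_cohort(n_patients = 20, seed = seed)
    conc <- detect_concordant_events(co)
    hist <- table(conc$per_patient_event_counts$n_events)
    tot <- events_from_distribution(setNames(as.numeric(hist), names(hist)))
    expect_identical(tot$n_patients, as.numeric(nrow(conc$per_patient_event_counts)))
    expect_identical(tot$n_events, as.numeric(nrow(conc$events)))
    # events per patient cannot exceed either assay's distinct gene count
    for (pid in conc$per_patient_event_counts$patient_id) {
      nd <- length(unique(co$dna_calls$gene[co$dna_calls$patient_id == pid]))
      nr <- length(unique(co$rna_calls$gene[co$rna_calls$patient_id == pid]))
      ne <- conc$per_patient_event_counts$n_events[
        conc$per_patient_event_counts$patient_id == pid]
      expect_lte(ne, min(nd, nr))
    }
  }
})

test_that("class breakdown counts sum to events and percentages to 100", {
  co <- cohort(
    make_patients(c("P1", "P2", "P3", "P4")),
    dplyr::bind_rows(
      dna_row("P1", "A", "copy_number_gain", 5),
      dna_row("P2", "B", "copy_number_gain", 7),
      dna_row("P3", "C", "missense_snv"),
      dna_row("P4", "D", "fusion_or_rearrangement")),
    dplyr::bind_rows(rna_row("P1", "A"), rna_row("P2", "B"),
                     rna_row("P3", "C"), rna_row("P4", "D"))
  )
  bd <- event_class_breakdown(detect_concordant_events(co))
  expect_identical(sum(bd$n), 4L)
  expect_equal(sum(bd$pct), 100)
  expect_equal(bd$pct[bd$primary_class == "copy_number_gain"], 50)
  expect_equal(bd$pct[bd$primary_class == "missense_snv"], 25)

  # recount oracle on a synthetic cohort
  conc <- detect_concordant_events(generate_cohort(simulation_config(n_patients = 50), seed = 7))
  bd2 <- event_class_breakdown(conc)
  expect_identical(sum(bd2$n), nrow(conc$events))
  tab <- table(conc$events$primary_class)
  for (cls in names(tab)) {
    expect_identical(bd2$n[bd2$primary_class == cls], as.integer(tab[[cls]]))
  }
})

test_that("copy-number/expression Spearman handles monotone, tied and sparse input", {
  mk <- function(cn, score) {
    co <- cohort(
      make_patients(sprintf("P%d", seq_along(cn))),
      dna_row(sprintf("P%d", seq_along(cn)), "G", "copy_number_gain", cn),
      rna_row(sprintf("P%d", seq_along(cn)), "G", "over", score))
    cn_expression_correlation(detect_concordant_events(co))
  }
  expect_equal(mk(c(1, 2, 3), c(10, 20, 30))$spearman_rho, 1)
  expect_equal(mk(c(1, 2, 3), c(30, 20, 10))$spearman_rho, -1)
  expect_identical(mk(c(1, 2), c(1, 2))$status, "insufficient_data")

  # 20 simulated pairs with ties vs hand midrank computation
  withr::with_seed(5, {
    cn <- sample(c(3, 4, 4, 6, 8), 20, replace = TRUE)
    sc <- cn * 10 + sample(c(0, 0, 5), 20, replace = TRUE)
  })
  expect_equal(mk(cn, sc)$spearman_rho, oracle_spearman(cn, sc), tolerance = 1e-12)
})

test_that("purity comparison: exact small-sample p, symmetry, and power", {
  ids <- sprintf("P%d", 1:6)
  co <- cohort(
    make_patients(ids, tumor_purity = c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3)),
    dna_row(ids[1:3], "KRAS"),
    rna_row(ids[1:3], "KRAS"))
  res <- purity_concordance_test(co)
  expect_equal(res$p_value, 0.1)  # enumerating all 20 label assignments
  expect_true(min(res$u, res$n_x * res$n_y - res$u) == 0)
  expect_identical(res$method, "exact")

  # same purity multiset in both groups: p = 1 under the tie-corrected
  # approximation
  co2 <- cohort(
    make_patients(ids, tumor_purity = rep(c(0.2, 0.5, 0.8), 2)),
    dna_row(ids[1:3], "KRAS"),
    rna_row(ids[1:3], "KRAS"))
  expect_gte(purity_concordance_test(co2)$p_value, 0.99)

  # missing purity excluded; empty group -> insufficient data
  co3 <- cohort(make_patients(ids, tumor_purity = NA_real_),
                dna_row(ids[1], "KRAS"), rna_row(ids[1], "KRAS"))
  expect_identical(purity_concordance_test(co3)$status, "insufficient_data")

  # planted +0.3 shift, n = 40/40: detected in >= 90% of 200 replicates
  hits <- withr::with_seed(99, {
    vapply(1:200, function(i) {
      a <- pmin(1, rbeta(40, 4, 4) + 0.3)
      b <- rbeta(40, 4, 4)
      mann_whitney_test(a, b)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})
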