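test_that("TTB counts distinct expression-altered genes and bins into strata", {
  co <- cohort(
    make_patients(c("P1", "P2", "P3")),
    NULL,
    dplyr::bind_rows(
      rna_row("P1", c("A", "B"), direction = c("over", "under")),
      rna_row("P2", c("A", "B", "C")),
      rna_row("P3", sprintf("G%d", 1:6))))
  ttb <- compute_ttb(co)
  expect_identical(ttb$ttb, c(2L, 3L, 6L))
  expect_identical(as.character(ttb$stratum), c("low", "mid", "high"))
  # conservation: total TTB equals the number of distinct (patient, gene) rows
  expect_identical(sum(ttb$ttb), nrow(dplyr::distinct(co$rna_calls, patient_id, gene)))

  # zero-call patients appear with ttb 0; custom breaks relabel
  co0 <- cohort(make_patients("P9"))
  t0 <- compute_ttb(co0, breaks = c(1, 3, 7))
  expect_identical(t0$ttb, 0L)
  expect_identical(as.character(t0$stratum), "0-1")
})

test_that("Kaplan-Meier estimates match closed form and a hand-built risk table", {
  km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  # all censored: flat at 1
  kmc <- km_estimate(c(2, 5, 7), c(FALSE, FALSE, FALSE))
  expect_true(all(kmc$survival == 1))

  # mixed censoring, n = 10: manual product-limit table with Greenwood SE
  times <- c(1, 1, 2, 3, 3, 4, 6, 6, 8, 9)
  events <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  got <- km_estimate(times, events)
  want <- oracle_km(times, events)
  expect_equal(got$time, want$time)
  expect_equal(got$survival, want$survival, tolerance = 1e-12)
  expect_equal(got$n_risk, want$n_risk)
  expect_equal(got$std_err, want$std_err, tolerance = 1e-10)

  # uncensored KM is the empirical survival function
  withr::with_seed(2, t10 <- rexp(30, 0.1))
  km10 <- km_estimate(t10, rep(TRUE, 30))
  ecdf_surv <- 1 - ecdf(t10)(km10$time)
  expect_equal(km10$survival, ecdf_surv, tolerance = 1e-12)

  expect_error(km_estimate(numeric(), logical()), "empty")
  expect_error(km_estimate(c(1, -2), c(TRUE, TRUE)), "non-negative")
})

test_that("median survival is the 0.5 crossing of the product-limit curve", {
  # S(t) sits exactly at 0.5 on [2, 3): median is the plateau midpoint
  expect_equal(km_median(c(1, 2, 3, 4), rep(TRUE, 4)), 2.5)
  expect_true(is.na(km_median(c(1, 2, 3), c(TRUE, FALSE, FALSE))))
})

test_that("log-rank agrees with a hand-computed risk-table statistic", {
  # identical multisets in two groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # three small groups, hand example
  times <- c(2, 5, 3, 8, 4, 9)
  events <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  grp <- rep(c("g1", "g2", "g3"), each = 2)
  lr <- logrank_test(times, events, grp)
  expect_identical(lr$df, 2L)
  expect_equal(lr$statistic, oracle_logrank_stat(times, events, grp),
               tolerance = 1e-8)

  # invariance under group relabeling
  relab <- c(g1 = "z", g2 = "x", g3 = "y")[grp]
  expect_equal(logrank_test(times, events, relab)$statistic, lr$statistic)

  # larger two-group case against the oracle
  withr::with_seed(11, {
    t2 <- rexp(40, rep(c(0.05, 0.12), each = 20))
    e2 <- runif(40) < 0.8
    g2 <- rep(c("a", "b"), each = 20)
  })
  expect_equal(logrank_test(t2, e2, g2)$statistic,
               oracle_logrank_stat(t2, e2, g2), tolerance = 1e-8)

  expect_error(logrank_test(1:3, c(TRUE, TRUE, TRUE), rep("a", 3)), "2 non-empty")
})

test_that("the log-rank statistic is calibrated under label permutation", {
  # For null datasets, the permutation p of the observed statistic (its rank
  # among statistics recomputed under label shuffles) should be uniform.
  perm_p <- withr::with_seed(29, {
    vapply(1:50, function(i) {
      times <- rexp(60, 0.08)
      events <- runif(60) < 0.8
      grp <- rep(c("a", "b", "c"), each = 20)
      obs <- logrank_test(times, events, grp)$statistic
      perm <- vapply(1:120, function(b) {
        logrank_test(times, events, sample(grp))$statistic
      }, numeric(1))
      (1 + sum(perm >= obs)) / (120 + 1)
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(perm_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("TTB survival object restricts to treated patients and summarises strata", {
  co <- generate_cohort(simulation_config(n_patients = 120), seed = 4)
  sv <- ttb_survival(co)
  expect_true(all(sv$records$patient_id %in%
                    co$patients$patient_id[co$patients$treated]))
  sv_all <- ttb_survival(co, treated_only = FALSE)
  expect_identical(nrow(sv_all$records), 120L)
  expect_true(all(sv$medians$n >= 1))
  expect_identical(sv$logrank$df, nrow(sv$medians) - 1L)
  # curves are non-increasing within stratum
  for (s in unique(sv$curves$stratum)) {
    expect_true(!is.unsorted(rev(sv$curves$survival[sv$curves$stratum == s])))
  }
  g <- glance(sv)
  expect_identical(nrow(g), 1L)
  expect_true("median_os_low" %in% names(g))
  expect_identical(tidy(sv), sv$curves)
})

test_that("TTB by PD-L1: exact small-sample p, ties, and power", {
  ids <- sprintf("P%d", 1:6)
  co <- cohort(
    make_patients(ids, pdl1_status = rep(c("negative", "positive"), each = 3)),
    NULL,
    dplyr::bind_rows(lapply(1:6, function(i) {
      rna_row(ids[i], sprintf("G%d", seq_len(i)))
    })))
  # negatives have TTB {1,2,3}, positives {4,5,6}
  res <- ttb_by_pdl1_test(co)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")
  expect_identical(res$median_ttb_negative, 2L)

  # identical multisets: p ~ 1 under the tie-corrected approximation
  co2 <- cohort(
    make_patients(ids, pdl1_status = rep(c("negative", "positive"), 3)),
    NULL,
    dplyr::bind_rows(lapply(1:6, function(i) {
      rna_row(ids[i], sprintf("G%d", seq_len(ceiling(i / 2))))
    })))
  expect_gte(ttb_by_pdl1_test(co2)$p_value, 0.99)

  # unknown PD-L1 is excluded from this test only
  co3 <- cohort(make_patients(ids, pdl1_status = c("negative", "unknown",
                                                   "unknown", "unknown",
                                                   "unknown", "positive")))
  res3 <- ttb_by_pdl1_test(co3)
  expect_identical(res3$n_x + res3$n_y, 2L)

  # planted shift of +2 genes, n = 60/60: detected in >= 90% of 200 replicates
  hits <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      neg <- rpois(60, 4)
      pos <- rpois(60, 2)
      mann_whitney_test(neg, pos)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("baseline chi-squared reproduces the printed comparisons with Yates", {
  # profiled-both vs DNA-only groups, characteristic present/absent
  rows <- list(
    age = list(m = rbind(c(126, 127), c(80, 105)), p = 0.207),
    sex = list(m = rbind(c(122, 131), c(90, 95)), p = 1),
    prior = list(m = rbind(c(128, 125), c(86, 99)), p = 0.452),
    ecog = list(m = rbind(c(30, 223), c(27, 158)), p = 0.486),
    mets = list(m = rbind(c(86, 167), c(49, 136)), p = 0.115)
  )
  for (r in rows) {
    expect_equal(round(baseline_chi2(r$m)$p_value, 3), r$p, tolerance = 1e-8)
  }
  # without the correction the age comparison is anticonservative
  expect_equal(round(baseline_chi2(rows$age$m, yates = FALSE)$p_value, 3), 0.174)
  # the floored correction is what drives the sex row to exactly 1
  expect_lt(baseline_chi2(rows$sex$m, yates = FALSE)$p_value, 1)

  expect_error(baseline_chi2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(baseline_chi2(c(1, 2, 3)), "2x2")
  # vector input fills the table by row
  expect_equal(baseline_chi2(c(126, 127, 80, 105))$p_value,
               baseline_chi2(rows$age$m)$p_value)
})
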