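# Truncated negative binomial sampler via inverse CDF (support 0..max).
rtrunc_nbinom <- function(n, size, mu, max) {
  u <- runif(n) * pnbinom(max, size = size, mu = mu)
  qnbinom(u, size = size, mu = mu)
}

zipf_weights <- function(n, exponent) {
  w <- seq_len(n)^(-exponent)
  w / sum(w)
}

#' Gene universes for simulated panels
#'
#' The simulated panels put a curated head of recurrently altered cancer
#' genes at the top of the frequency ranking (the ranking drives the
#' Zipf-like sampling weights) and pad with synthetic symbols (`GD###`,
#' `GR###`). The two universes share the common driver genes so that
#' same-gene concordance is observable; `VEGFA` sits mid-ranking on the RNA
#' side, where its baseline frequency makes chance co-occurrence with common
#' DNA drivers rare.
#'
#' @param n Number of genes.
#' @return Character vector of length `n`, ordered from most to least
#'   frequently altered.
#' @export
dna_gene_universe <- function(n = 242) {
  head_genes <- c(
    "TP53", "KRAS", "CDKN2A", "PIK3CA", "APC", "CDKN2B", "ARID1A", "MYC",
    "PTEN", "KMT2D", "EGFR", "CCND1", "ERBB2", "AR", "ESR1", "CDK4", "RB1",
    "AKT2", "FGFR1", "MDM2", "BRAF", "SMAD4", "NF1", "ATM", "STK11", "BRCA2",
    "CCNE1", "FGFR2", "IDH1", "NRAS"
  )
  pad_universe(head_genes, n, "GD")
}

#' @rdname dna_gene_universe
#' @export
rna_gene_universe <- function(n = 52) {
  head_genes <- c(
    "MET", "CDK6", "AURKA", "IGF1R", "BCL2", "CCND2", "MCL1", "NOTCH1",
    "TERT", "JUN", "CDKN2A", "VEGFA", "AR", "CDKN2B", "ESR1", "KRAS",
    "CDK4", "PIK3CA", "AKT2", "TP53", "CCND1", "ERBB2", "EGFR", "MYC",
    "MDM2", "FGFR1", "CCNE1", "PTEN", "RB1", "FGFR2", "BRAF", "MDM4"
  )
  pad_universe(head_genes, n, "GR")
}

pad_universe <- function(head_genes, n, prefix) {
  if (n <= length(head_genes)) return(head_genes[seq_len(n)])
  c(head_genes, sprintf("%s%03d", prefix, seq_len(n - length(head_genes))))
}

#' Configuration for the synthetic paired-profiling cohort generator
#'
#' Every generator parameter with its calibrated default. The defaults
#' emulate the statistical structure of a 253-patient clinical cohort with
#' paired DNA/RNA profiling reports: per-patient altered-gene counts with
#' medians 4 (DNA, support 0-21) and 2 (RNA, support 0-9), a DNA
#' alteration-class mixture of 42.9/30.4/23.8/2.9% (frameshift or stop-gain /
#' copy number / missense / fusion), an 87.7/12.3% over/under expression
#' split, purity-modulated coupling of copy-number calls to same-gene
#' expression calls with rank-correlated copy number and expression score,
#' one planted cross-gene association (TP53 DNA with VEGFA overexpression),
#' and TTB-stratum-specific exponential survival with medians 9.8/11.9/6.7
#' months and 20% random censoring.
#'
#' @param n_patients,n_dna_genes,n_rna_genes Cohort and panel sizes.
#' @param dna_count_dist,rna_count_dist Truncated negative-binomial
#'   parameters (`size`, `mu`, `max`) for per-patient distinct altered-gene
#'   counts.
#' @param class_mixture Named probabilities over DNA call classes; the
#'   `copy_number` entry is split into gain/loss by `cn_gain_fraction`.
#' @param cn_gain_fraction Fraction of copy-number calls that are gains.
#' @param rna_direction_mixture Named probabilities for `over`/`under`.
#' @param concordance_coupling Base probability that a copy-number DNA call
#'   in an RNA-panel gene induces the matching same-gene expression call;
#'   multiplied by the patient's tumor purity.
#' @param coupling_classes DNA classes eligible for coupling (copy-number
#'   classes by default; gain couples to overexpression, loss to
#'   underexpression).
#' @param cn_expression_spearman Target Spearman correlation between copy
#'   number and expression score among concordant copy-number events.
#' @param cn_expression_latent_rho Pearson correlation of the Gaussian copula
#'   linking copy number to expression score in coupled calls; set above the
#'   grade correlation implied by `cn_expression_spearman` to offset dilution
#'   from chance same-gene co-occurrences whose scores are uncoupled.
#' @param planted_pairs Tibble (`dna_gene`, `rna_gene`, `odds_multiplier`)
#'   of cross-gene associations to plant by inflating co-occurrence odds;
#'   `NULL` for none.
#' @param purity_dist `shape1`, `shape2` of the Beta tumor-purity
#'   distribution.
#' @param ttb_breaks Inclusive upper TTB bounds defining survival strata.
#' @param stratum_median_os Named (by stratum label) median OS in months.
#' @param censoring_rate Expected fraction of patients right-censored.
#' @param pdl1_logit_intercept,pdl1_logit_slope Logistic model for
#'   P(PD-L1 negative) as a function of TTB (positive slope makes high-TTB
#'   tumors more often PD-L1 negative).
#' @param pdl1_unknown_rate Fraction of patients with unknown PD-L1 status.
#' @param treated_fraction Probability a patient is flagged treated.
#' @param gene_freq_exponent Zipf exponent of the gene-frequency rankings.
#' @param seed Default seed used by [generate_cohort()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 253L,
    n_dna_genes = 242L,
    n_rna_genes = 52L,
    dna_count_dist = list(size = 4, mu = 4.4, max = 21L),
    rna_count_dist = list(size = 2, mu = 2.4, max = 9L),
    class_mixture = c(frameshift_or_stopgain = 0.429, copy_number = 0.304,
                      missense_snv = 0.238, fusion_or_rearrangement = 0.029),
    cn_gain_fraction = 0.75,
    rna_direction_mixture = c(over = 0.877, under = 0.123),
    concordance_coupling = 0.42,
    coupling_classes = copy_number_classes(),
    cn_expression_spearman = 0.72,
    cn_expression_latent_rho = 0.88,
    planted_pairs = tibble(dna_gene = "TP53", rna_gene = "VEGFA",
                           odds_multiplier = 12),
    purity_dist = c(shape1 = 2.5, shape2 = 1.5),
    ttb_breaks = c(2L, 5L),
    stratum_median_os = c(low = 9.8, mid = 11.9, high = 6.7),
    censoring_rate = 0.2,
    pdl1_logit_intercept = -0.6,
    pdl1_logit_slope = 0.25,
    pdl1_unknown_rate = 0.08,
    treated_fraction = 217 / 253,
    gene_freq_exponent = 0.9,
    seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with(cfg, {
    if (n_patients < 0) abort("n_patients must be non-negative")
    for (nm in c("n_dna_genes", "n_rna_genes")) {
      if (cfg[[nm]] < 1) abort(sprintf("%s must be positive", nm))
    }
    if (abs(sum(class_mixture) - 1) > 1e-6) abort("class_mixture must sum to 1")
    if (abs(sum(rna_direction_mixture) - 1) > 1e-6) {
      abort("rna_direction_mixture must sum to 1")
    }
    ok_classes <- c(dna_alteration_classes(), "copy_number")
    if (!all(names(class_mixture) %in% ok_classes)) {
      abort("class_mixture names must be DNA alteration classes (or 'copy_number')")
    }
    if (!setequal(names(rna_direction_mixture), rna_directions())) {
      abort("rna_direction_mixture must be named over/under")
    }
    probs <- c(class_mixture, rna_direction_mixture, concordance_coupling,
               cn_gain_fraction, censoring_rate, pdl1_unknown_rate,
               treated_fraction)
    if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
    if (abs(cn_expression_latent_rho) > 1) abort("cn_expression_latent_rho must lie in [-1, 1]")
    if (dna_count_dist$max > n_dna_genes) {
      abort("dna_count_dist support exceeds n_dna_genes")
    }
    if (rna_count_dist$max > n_rna_genes) {
      abort("rna_count_dist support exceeds n_rna_genes")
    }
    labels <- ttb_stratum_labels(ttb_breaks)
    if (!setequal(names(stratum_median_os), labels)) {
      abort(sprintf("stratum_median_os must be named by the stratum labels: %s",
                    paste(labels, collapse = ", ")))
    }
    if (any(stratum_median_os <= 0)) abort("stratum medians must be positive")
    if (!is.null(planted_pairs)) {
      check_required_columns(planted_pairs,
                             c("dna_gene", "rna_gene", "odds_multiplier"),
                             "planted_pairs")
      if (any(planted_pairs$odds_multiplier < 1)) {
        abort("planted odds multipliers must be >= 1")
      }
    }
  })
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d patients, %d DNA genes, %d RNA genes, seed %d\n",
    x$n_patients, x$n_dna_genes, x$n_rna_genes, x$seed))
  invisible(x)
}

# Tumor-type mixture loosely matching a heavily pretreated phase-I cohort.
tumor_type_mixture <- function() {
  c(colorectal = 0.21, head_and_neck = 0.12, sarcoma = 0.12, breast = 0.09,
    gastrointestinal_other = 0.09, pancreas = 0.07, prostate = 0.07,
    lung = 0.05, ovarian = 0.04, endocrine = 0.04, gynecologic = 0.04,
    melanoma = 0.02, brain = 0.02, other = 0.12)
}

#' Generate a synthetic paired DNA/RNA profiling cohort
#'
#' Deterministic given `seed`. Per patient: draw tumor purity and baseline
#' covariates; draw the number of DNA-altered genes from the truncated
#' negative binomial and the genes themselves with Zipf-like frequency
#' weights (a minority of recurrent drivers dominate); assign call classes
#' from the class mixture with numeric copy-number values for gains and
#' losses; draw baseline RNA calls the same way with directions from the
#' direction mixture. Copy-number calls in RNA-panel genes then induce the
#' matching same-gene expression call (gain to over, loss to under) with
#' probability `concordance_coupling * purity`, with expression score tied
#' to copy number through a Gaussian copula. Planted pairs inflate cross-gene
#' co-occurrence to the configured odds multiplier. Overall survival is drawn
#' exponentially with the configured median for the patient's realized TTB
#' stratum and right-censored at the configured rate; PD-L1 negativity
#' follows a logistic model in TTB.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`). The global RNG state
#'   is left untouched.
#' @return A validated [cohort()] object.
#' @export
generate_cohort <- function(config = simulation_config(), seed = config$seed) {
  cfg <- validate_simulation_config(config)
  withr::with_seed(as.integer(seed), generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  ids <- if (n) sprintf("PT%04d", seq_len(n)) else character()
  purity <- rbeta(n, cfg$purity_dist[["shape1"]], cfg$purity_dist[["shape2"]])

  tt <- tumor_type_mixture()
  patients <- tibble(
    patient_id = ids,
    tumor_type = if (n) sample(names(tt), n, replace = TRUE, prob = tt) else character(),
    age_years = pmin(84, pmax(20, round(rnorm(n, mean = 59, sd = 12)))),
    sex = if (n) sample(sex_levels(), n, replace = TRUE, prob = c(0.48, 0.52)) else character(),
    n_prior_therapies = stats::rpois(n, 4.2),
    ecog = rbinom(n, 1L, 0.88),
    n_metastatic_sites = stats::rpois(n, 2.2),
    albumin_low = rbinom(n, 1L, 0.11) == 1L,
    ldh_high = ifelse(runif(n) < 0.07, NA, rbinom(n, 1L, 0.54) == 1L),
    tumor_purity = purity
  )

  dna_univ <- dna_gene_universe(cfg$n_dna_genes)
  rna_univ <- rna_gene_universe(cfg$n_rna_genes)
  w_dna <- zipf_weights(cfg$n_dna_genes, cfg$gene_freq_exponent)
  w_rna <- zipf_weights(cfg$n_rna_genes, cfg$gene_freq_exponent)

  # --- DNA calls ---------------------------------------------------------
  k_dna <- rtrunc_nbinom(n, cfg$dna_count_dist$size, cfg$dna_count_dist$mu,
                         cfg$dna_count_dist$max)
  dna <- tibble(
    patient_id = rep(ids, times = k_dna),
    gene = as.character(unlist(lapply(k_dna, function(k) {
      if (k == 0) character() else sample(dna_univ, k, prob = w_dna)
    }), use.names = FALSE))
  )
  meta <- if (nrow(dna)) {
    sample(names(cfg$class_mixture), nrow(dna), replace = TRUE,
           prob = cfg$class_mixture)
  } else character()
  is_meta_cn <- meta == "copy_number"
  meta[is_meta_cn] <- ifelse(rbinom(sum(is_meta_cn), 1L, cfg$cn_gain_fraction) == 1L,
                             "copy_number_gain", "copy_number_loss")
  dna$alteration_class <- meta
  dna$copy_number <- NA_real_
  gain <- dna$alteration_class == "copy_number_gain"
  loss <- dna$alteration_class == "copy_number_loss"
  dna$copy_number[gain] <- 2 + stats::rlnorm(sum(gain), log(2.5), 0.5)
  dna$copy_number[loss] <- runif(sum(loss), 0, 1.5)

  # --- baseline RNA calls ------------------------------------------------
  k_rna <- rtrunc_nbinom(n, cfg$rna_count_dist$size, cfg$rna_count_dist$mu,
                         cfg$rna_count_dist$max)
  rna_base <- tibble(
    patient_id = rep(ids, times = k_rna),
    gene = as.character(unlist(lapply(k_rna, function(k) {
      if (k == 0) character() else sample(rna_univ, k, prob = w_rna)
    }), use.names = FALSE))
  )
  over <- runif(nrow(rna_base)) < cfg$rna_direction_mixture[["over"]]
  rna_base$direction <- ifelse(over, "over", "under")
  rna_base$expression_score <- ifelse(over, runif(nrow(rna_base), 55, 100),
                                      runif(nrow(rna_base), 0, 45))
  rna_base$origin <- "baseline"

  # --- purity-modulated same-gene coupling -------------------------------
  cand <- dna |>
    filter(.data$alteration_class %in% cfg$coupling_classes,
           .data$gene %in% rna_univ)
  rna_coupled <- if (nrow(cand)) {
    p <- cfg$concordance_coupling * purity[match(cand$patient_id, ids)]
    cand <- cand[runif(nrow(cand)) < p, , drop = FALSE]
    if (nrow(cand)) {
      score <- coupled_expression_score(cand$copy_number, cand$alteration_class,
                                        cfg$cn_expression_latent_rho)
      tibble(
        patient_id = cand$patient_id, gene = cand$gene,
        direction = ifelse(cand$alteration_class == "copy_number_loss",
                           "under", "over"),
        expression_score = score, origin = "coupled"
      )
    } else NULL
  } else NULL

  # --- planted cross-gene associations -----------------------------------
  rna_now <- bind_rows(rna_coupled, rna_base)
  rna_planted <- NULL
  if (!is.null(cfg$planted_pairs) && nrow(cfg$planted_pairs) && n > 0) {
    for (i in seq_len(nrow(cfg$planted_pairs))) {
      dg <- normalize_gene_symbol(cfg$planted_pairs$dna_gene[i])
      rg <- normalize_gene_symbol(cfg$planted_pairs$rna_gene[i])
      mult <- cfg$planted_pairs$odds_multiplier[i]
      has_rg <- ids %in% rna_now$patient_id[rna_now$gene == rg]
      q <- mean(has_rg)
      target <- mult * q / (1 + (mult - 1) * q)
      p_extra <- if (q < 1) max(0, (target - q) / (1 - q)) else 0
      eligible <- ids[ids %in% dna$patient_id[dna$gene == dg] & !has_rg]
      pick <- eligible[runif(length(eligible)) < p_extra]
      if (length(pick)) {
        add <- tibble(
          patient_id = pick, gene = rg, direction = "over",
          expression_score = runif(length(pick), 55, 100), origin = "planted"
        )
        rna_planted <- bind_rows(rna_planted, add)
        rna_now <- bind_rows(rna_now, add)
      }
    }
  }

  # Collapse duplicates with priority coupled > planted > baseline, then
  # respect the per-patient support cap of the RNA count distribution.
  rna <- bind_rows(rna_coupled, rna_planted, rna_base) |>
    distinct(.data$patient_id, .data$gene, .keep_all = TRUE) |>
    group_by(.data$patient_id) |>
    dplyr::slice_head(n = cfg$rna_count_dist$max) |>
    ungroup() |>
    select(-"origin")

  # --- TTB, survival, PD-L1, treatment -----------------------------------
  ttb <- integer(n)
  if (nrow(rna)) {
    cnt <- count(distinct(rna, .data$patient_id, .data$gene), .data$patient_id)
    ttb[match(cnt$patient_id, ids)] <- cnt$n
  }
  labels <- ttb_stratum_labels(cfg$ttb_breaks)
  stratum <- as.character(cut(ttb, breaks = c(-Inf, cfg$ttb_breaks, Inf),
                              labels = labels))
  rate <- log(2) / cfg$stratum_median_os[stratum]
  t_death <- rexp(n, rate)
  os_months <- t_death
  os_event <- rep(TRUE, n)
  if (cfg$censoring_rate > 0) {
    c_rate <- rate * cfg$censoring_rate / (1 - cfg$censoring_rate)
    t_cens <- rexp(n, c_rate)
    os_event <- t_death <= t_cens
    os_months <- pmin(t_death, t_cens)
  }
  p_neg <- plogis(cfg$pdl1_logit_intercept + cfg$pdl1_logit_slope * ttb)
  pdl1 <- ifelse(runif(n) < p_neg, "negative", "positive")
  pdl1[runif(n) < cfg$pdl1_unknown_rate] <- "unknown"

  patients <- patients |>
    mutate(
      pdl1_status = pdl1,
      treated = runif(n) < cfg$treated_fraction,
      os_months = os_months,
      os_event = os_event
    )
  if (n == 0) {
    patients <- patients[0, ]
    patients$pdl1_status <- character()
    patients$treated <- logical()
    patients$os_months <- numeric()
    patients$os_event <- logical()
  }
  cohort(patients, arrange(dna, .data$patient_id, .data$gene),
         arrange(rna, .data$patient_id, .data$gene))
}

# Expression percentile tied to copy number through a Gaussian copula.
# Copy number is mapped to a grade in (0, 1) — losses below 0.5, gains
# above — so low copy number pairs with low expression percentiles.
coupled_expression_score <- function(copy_number, class, rho) {
  grade <- ifelse(
    class == "copy_number_loss",
    0.5 * pmin(copy_number / 2, 1 - 1e-9),
    0.5 + 0.5 * stats::plnorm(pmax(copy_number - 2, 1e-12), log(2.5), 0.5)
  )
  z <- qnorm(pmin(pmax(grade, 1e-9), 1 - 1e-9))
  latent <- rho * z + sqrt(1 - rho^2) * rnorm(length(z))
  100 * pnorm(latent)
}

#' Compare realized cohort summaries with the generator configuration
#'
#' Recomputes the quantities the generator is calibrated to — per-patient
#' altered-gene medians and supports, class and direction mixtures, the
#' copy-number/expression Spearman correlation among concordant events, and
#' per-stratum Kaplan-Meier median OS — and pairs each with its configured
#' value and a pass/fail flag at the stated tolerance.
#'
#' @param x A [cohort()] object (typically from [generate_cohort()]).
#' @param config The [simulation_config()] used to generate it.
#' @return Tibble with `quantity`, `configured`, `realized`, `tolerance`,
#'   `pass`. Empty for an empty cohort.
#' @export
calibration_report <- function(x, config = simulation_config()) {
  stopifnot(inherits(x, "cohort"))
  cfg <- validate_simulation_config(config)
  if (nrow(x$patients) == 0) {
    return(tibble(quantity = character(), configured = numeric(),
                  realized = numeric(), tolerance = numeric(), pass = logical()))
  }
  row <- function(quantity, configured, realized, tolerance) {
    tibble(quantity = quantity, configured = configured, realized = realized,
           tolerance = tolerance,
           pass = is.finite(realized) & abs(realized - configured) <= tolerance)
  }
  count_median <- function(dist) {
    # median of the truncated counting distribution
    qnbinom(0.5 * pnbinom(dist$max, size = dist$size, mu = dist$mu),
            size = dist$size, mu = dist$mu)
  }
  dna_counts <- altered_gene_counts(x, "dna")$n_genes
  rna_counts <- altered_gene_counts(x, "rna")$n_genes

  cm <- cfg$class_mixture * 100
  cls <- x$dna_calls$alteration_class
  cls[cls %in% copy_number_classes()] <- "copy_number"
  realized_cm <- 100 * as.vector(table(factor(cls, levels = names(cm)))) / max(1, length(cls))
  dirs <- 100 * mean(x$rna_calls$direction == "over")

  conc <- detect_concordant_events(x)
  rho <- cn_expression_correlation(conc)$spearman_rho

  surv <- ttb_survival(x, breaks = cfg$ttb_breaks, treated_only = FALSE)
  med <- setNames(surv$medians$median_os, surv$medians$stratum)
  cfg_med <- cfg$stratum_median_os

  bind_rows(
    row("median_dna_genes_per_patient", count_median(cfg$dna_count_dist),
        stats::median(dna_counts), 0),
    row("median_rna_genes_per_patient", count_median(cfg$rna_count_dist),
        stats::median(rna_counts), 0),
    row("max_dna_genes_per_patient", cfg$dna_count_dist$max, max(dna_counts),
        cfg$dna_count_dist$max),
    row("max_rna_genes_per_patient", cfg$rna_count_dist$max, max(rna_counts),
        cfg$rna_count_dist$max),
    bind_rows(lapply(names(cm), function(nm) {
      row(paste0("pct_class_", nm), unname(cm[nm]),
          realized_cm[match(nm, names(cm))], 3)
    })),
    row("pct_direction_over", 100 * cfg$rna_direction_mixture[["over"]], dirs, 3),
    row("cn_expression_spearman", cfg$cn_expression_spearman,
        if (is.na(rho)) NA_real_ else rho, 0.1),
    bind_rows(lapply(names(cfg_med), function(s) {
      row(paste0("median_os_", s), unname(cfg_med[s]),
          if (s %in% names(med)) unname(med[s]) else NA_real_, 2.5)
    }))
  )
}
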