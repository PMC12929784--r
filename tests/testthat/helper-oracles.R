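# Independent oracles, kept deliberately naive: explicit enumeration and
# hand-rolled formulas, sharing no code path with the package internals.

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins, probabilities from explicit binomial coefficients.
oracle_fisher_p <- function(n00, n10, n01, n11) {
  n <- n00 + n10 + n01 + n11
  kd <- n10 + n11 # row margin: DNA-altered
  kr <- n01 + n11 # column margin: RNA-altered
  if (kd == 0 || kr == 0 || kd == n || kr == n) return(1)
  ks <- max(0, kd + kr - n):min(kd, kr)
  prob_of <- function(k) {
    exp(lchoose(kr, k) + lchoose(n - kr, kd - k) - lchoose(n, kd))
  }
  probs <- vapply(ks, prob_of, numeric(1))
  p_obs <- probs[ks == n11]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg by the literal step-up definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / rank_j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i] | abs(p - p[i]) < 1e-15)
    min(1, min(m * p[js] / ranks[js]))
  }, numeric(1))
}

# Upper-tail hypergeometric by explicit summation of binomial coefficients.
oracle_hyper_upper <- function(n_universe, k_set, n_query, overlap) {
  ks <- overlap:min(k_set, n_query)
  if (overlap > min(k_set, n_query)) return(0)
  sum(vapply(ks, function(k) {
    exp(lchoose(k_set, k) + lchoose(n_universe - k_set, n_query - k) -
          lchoose(n_universe, n_query))
  }, numeric(1)))
}

# Concordant events by brute-force double loop over every patient and every
# gene seen anywhere in the cohort.
oracle_concordant_events <- function(cohort) {
  all_genes <- sort(unique(c(cohort$dna_calls$gene, cohort$rna_calls$gene)))
  out <- list()
  for (pid in cohort$patients$patient_id) {
    dg <- cohort$dna_calls$gene[cohort$dna_calls$patient_id == pid]
    rg <- cohort$rna_calls$gene[cohort$rna_calls$patient_id == pid]
    for (g in all_genes) {
      if (g %in% dg && g %in% rg) {
        out[[length(out) + 1L]] <- data.frame(patient_id = pid, gene = g)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), gene = character()))
  }
  do.call(rbind, out)
}

# 2x2 contingency cells by per-patient membership scan.
oracle_contingency <- function(cohort, dna_gene, rna_gene) {
  cells <- c(n00 = 0L, n10 = 0L, n01 = 0L, n11 = 0L)
  for (pid in cohort$patients$patient_id) {
    d <- dna_gene %in% cohort$dna_calls$gene[cohort$dna_calls$patient_id == pid]
    r <- rna_gene %in% cohort$rna_calls$gene[cohort$rna_calls$patient_id == pid]
    cell <- paste0("n", as.integer(d), as.integer(r))
    cells[cell] <- cells[cell] + 1L
  }
  cells
}

# Spearman correlation by hand: midranks then the Pearson formula on ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x) # rank() uses midranks for ties
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Product-limit estimator built from an explicit risk table (deaths before
# censorings at tied times) with Greenwood variance.
oracle_km <- function(times, events) {
  ord <- order(times, !events) # deaths first within a tied time
  times <- times[ord]
  events <- events[ord]
  utimes <- sort(unique(times))
  s <- 1
  gw <- 0
  rows <- list()
  for (t in utimes) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    c_ <- sum(times == t & !events)
    if (d > 0) {
      s <- s * (1 - d / n_risk)
      gw <- gw + d / (n_risk * (n_risk - d))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time = t, n_risk = n_risk, n_event = d, n_censor = c_,
      survival = s, std_err = s * sqrt(gw)
    )
  }
  do.call(rbind, rows)
}

# K-sample log-rank statistic from the risk table: observed minus expected
# event counts with the hypergeometric covariance, quadratic form on the
# first k-1 groups.
oracle_logrank_stat <- function(times, events, group) {
  group <- factor(group)
  k <- nlevels(group)
  o_minus_e <- numeric(k)
  v <- matrix(0, k, k)
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g), numeric(1))
    d_g <- vapply(levels(group), function(g) sum(times == t & events & group == g),
                  numeric(1))
    o_minus_e <- o_minus_e + d_g - d * n_g / n
    if (n > 1) {
      p <- n_g / n
      v <- v + d * (n - d) / (n - 1) * (diag(p) - outer(p, p))
    }
  }
  idx <- seq_len(k - 1)
  drop(t(o_minus_e[idx]) %*% solve(v[idx, idx, drop = FALSE]) %*% o_minus_e[idx])
}

# Expected fraction of pairs with two-sided Fisher p < alpha under the null,
# given the margins: sums hypergeometric point masses over the outcomes whose
# p-value clears alpha (the attainable level of each discrete test).
oracle_null_exceedance <- function(kd, kr, n, alpha = 0.05) {
  key <- paste(kd, kr)
  first <- !duplicated(key)
  e_first <- mapply(function(K1, K2) {
    if (K1 <= 0 || K2 <= 0 || K1 >= n || K2 >= n) return(0)
    ks <- max(0, K1 + K2 - n):min(K1, K2)
    probs <- vapply(ks, function(k) {
      exp(lchoose(K2, k) + lchoose(n - K2, K1 - k) - lchoose(n, K1))
    }, numeric(1))
    pvals <- vapply(seq_along(ks), function(i) {
      sum(probs[probs <= probs[i] * (1 + 1e-7)])
    }, numeric(1))
    sum(probs[pvals < alpha])
  }, kd[first], kr[first])
  unname(e_first[match(key, key[first])])
}
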