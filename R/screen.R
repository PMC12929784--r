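# patient x gene logical membership matrix (distinct-gene presence)
membership_matrix <- function(calls, patient_ids, genes) {
  m <- matrix(FALSE, nrow = length(patient_ids), ncol = length(genes),
              dimnames = list(patient_ids, genes))
  if (nrow(calls)) {
    pg <- distinct(calls, .data$patient_id, .data$gene)
    m[cbind(match(pg$patient_id, patient_ids), match(pg$gene, genes))] <- TRUE
  }
  m
}

#' Build the 2x2 contingency table for one DNA-gene x RNA-gene pair
#'
#' Cells classify every patient in the cohort by presence/absence of any DNA
#' alteration in `dna_gene` and any expression alteration in `rna_gene`:
#' `n00` neither, `n10` DNA only, `n01` RNA only, `n11` both. Membership is
#' judged per patient on distinct-gene presence, so multiple calls in the
#' same gene count once. A gene absent from the cohort simply yields a zero
#' margin.
#'
#' @param x A [cohort()] object.
#' @param dna_gene,rna_gene Gene symbols (normalized with
#'   [normalize_gene_symbol()] before matching).
#' @return One-row tibble: `dna_gene`, `rna_gene`, `n00`, `n10`, `n01`,
#'   `n11`; the four cells sum to the number of patients.
#' @export
build_contingency <- function(x, dna_gene, rna_gene) {
  stopifnot(inherits(x, "cohort"))
  dna_gene <- normalize_gene_symbol(dna_gene)
  rna_gene <- normalize_gene_symbol(rna_gene)
  ids <- x$patients$patient_id
  in_dna <- ids %in% filter(x$dna_calls, .data$gene == dna_gene)$patient_id
  in_rna <- ids %in% filter(x$rna_calls, .data$gene == rna_gene)$patient_id
  tibble(
    dna_gene = dna_gene, rna_gene = rna_gene,
    n00 = sum(!in_dna & !in_rna), n10 = sum(in_dna & !in_rna),
    n01 = sum(!in_dna & in_rna), n11 = sum(in_dna & in_rna)
  )
}

# Minimum-likelihood two-sided Fisher p for vectors of tables given by
# n11 and margins (kd = n11 + n10, kr = n11 + n01) out of n patients.
# Null: n11 ~ Hypergeom(N = n, K = kr, draws = kd). The two-sided p sums the
# probabilities of all tables with the same margins whose probability does
# not exceed that of the observed table (with a small relative tolerance for
# floating-point equality, as is conventional).
fisher_p_minlike <- function(n11, kd, kr, n) {
  stopifnot(length(kd) == length(n11), length(kr) == length(n11))
  key <- paste(n11, kd, kr, sep = ":")
  first <- !duplicated(key)
  p_first <- mapply(function(x11, K1, K2) {
    if (K1 <= 0 || K2 <= 0 || K1 >= n || K2 >= n) return(1)
    lo <- max(0L, K1 + K2 - n)
    hi <- min(K1, K2)
    d <- stats::dhyper(lo:hi, K2, n - K2, K1)
    min(1, sum(d[d <= d[x11 - lo + 1L] * (1 + 1e-7)]))
  }, n11[first], kd[first], kr[first])
  unname(p_first[match(key, key[first])])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Implements the minimum-likelihood two-sided rule: the p-value is the sum
#' of hypergeometric probabilities, over all tables with the observed
#' margins, of the tables whose probability does not exceed that of the
#' observed table. The odds ratio is the sample cross-product
#' `(n11 * n00) / (n10 * n01)` (`Inf` when the denominator is zero but the
#' numerator positive). A table with a zero row or column margin is
#' degenerate: `p = 1` and the odds ratio is flagged undefined (`NA`).
#'
#' @param n00,n10,n01,n11 Cell counts (vectors of equal length are accepted);
#'   `n00` = neither alteration, `n10` = DNA only, `n01` = RNA only, `n11` =
#'   both. A single 2x2 matrix `matrix(c(n00, n10, n01, n11), 2)` may be
#'   passed as `n00` instead.
#' @return Tibble with `odds_ratio`, `p_value` and `degenerate` (zero-margin
#'   flag), one row per input table.
#' @examples
#' fisher_exact_two_sided(3, 1, 1, 3) # p = 34/70
#' @export
fisher_exact_two_sided <- function(n00, n10 = NULL, n01 = NULL, n11 = NULL) {
  if (is.matrix(n00)) {
    stopifnot(all(dim(n00) == 2))
    m <- n00
    n00 <- m[1, 1]; n10 <- m[2, 1]; n01 <- m[1, 2]; n11 <- m[2, 2]
  }
  cells <- cbind(n00, n10, n01, n11)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    abort("cell counts must be non-negative integers")
  }
  n <- n00 + n10 + n01 + n11
  kd <- n10 + n11
  kr <- n01 + n11
  degenerate <- kd == 0 | kr == 0 | kd == n | kr == n
  num <- as.numeric(n11) * as.numeric(n00)
  den <- as.numeric(n10) * as.numeric(n01)
  or <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  or[degenerate] <- NA_real_
  p <- mapply(function(x11, K1, K2, ni) {
    fisher_p_minlike(x11, K1, K2, ni)
  }, n11, kd, kr, n)
  tibble(odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across a family of p-values; the
#' output preserves input order and is monotone in p. Thin, validated front
#' end to `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Exhaustive DNA-gene x RNA-gene association screen
#'
#' Tests every pair of (gene reported altered by DNA profiling) x (gene
#' reported altered by RNA profiling) for association across patients:
#' a 2x2 presence/absence contingency table per pair, a two-sided Fisher
#' exact test ([fisher_exact_two_sided()]), and Benjamini-Hochberg
#' adjustment across the full family of pairs — including zero-margin pairs,
#' which contribute `p = 1`. A pair whose two symbols are identical is a
#' *concordant pair*; all others are discordant pairs.
#'
#' @param x A [cohort()] object with at least one DNA gene and one RNA gene.
#' @param alpha Significance threshold recorded on the result (default 0.05);
#'   used by [partition_significant()] and the report.
#' @return A tibble of class `gene_pair_screen`, one row per pair, ordered by
#'   (`dna_gene`, `rna_gene`): contingency cells, `odds_ratio`, `p_value`,
#'   `adjusted_p`, `is_concordant_pair`. The row count is always
#'   (number of unique DNA genes) x (number of unique RNA genes).
#' @export
run_screen <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cohort"))
  ids <- x$patients$patient_id
  n <- length(ids)
  dna_genes <- sort(unique(x$dna_calls$gene))
  rna_genes <- sort(unique(x$rna_calls$gene))
  if (!length(dna_genes) || !length(rna_genes)) {
    warn("empty gene universe on at least one assay; returning zero pairs")
    out <- tibble(
      dna_gene = character(), rna_gene = character(),
      n00 = integer(), n10 = integer(), n01 = integer(), n11 = integer(),
      odds_ratio = numeric(), p_value = numeric(), adjusted_p = numeric(),
      is_concordant_pair = logical()
    )
    return(new_gene_pair_screen(out, alpha, n))
  }
  md <- membership_matrix(x$dna_calls, ids, dna_genes)
  mr <- membership_matrix(x$rna_calls, ids, rna_genes)
  n11 <- crossprod(md, mr)                # |Gd| x |Gr|
  kd <- colSums(md)
  kr <- colSums(mr)
  grid <- tibble(
    dna_gene = rep(dna_genes, times = length(rna_genes)),
    rna_gene = rep(rna_genes, each = length(dna_genes)),
    n11 = as.integer(n11),
    kd = rep(as.integer(kd), times = length(rna_genes)),
    kr = rep(as.integer(kr), each = length(dna_genes))
  )
  grid <- mutate(grid,
    n10 = .data$kd - .data$n11,
    n01 = .data$kr - .data$n11,
    n00 = n - .data$kd - .data$kr + .data$n11
  )
  num <- as.numeric(grid$n11) * as.numeric(grid$n00)
  den <- as.numeric(grid$n10) * as.numeric(grid$n01)
  degenerate <- grid$kd == 0 | grid$kr == 0 | grid$kd == n | grid$kr == n
  or <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  or[degenerate] <- NA_real_
  p <- fisher_p_minlike(grid$n11, grid$kd, grid$kr, n)
  out <- grid |>
    mutate(
      odds_ratio = or, p_value = p, adjusted_p = bh_adjust(p),
      is_concordant_pair = .data$dna_gene == .data$rna_gene
    ) |>
    select("dna_gene", "rna_gene", "n00", "n10", "n01", "n11",
           "odds_ratio", "p_value", "adjusted_p", "is_concordant_pair") |>
    arrange(.data$dna_gene, .data$rna_gene)
  new_gene_pair_screen(out, alpha, n)
}

new_gene_pair_screen <- function(df, alpha, n_patients) {
  structure(df, alpha = alpha, n_patients = n_patients,
            class = c("gene_pair_screen", class(df)))
}

#' Rank screen results by significance
#'
#' Deterministic ordering: adjusted p, then raw p, then lexicographic
#' (`dna_gene`, `rna_gene`).
#'
#' @param results A `gene_pair_screen` tibble.
#' @return The same tibble, ranked.
#' @export
rank_pairs <- function(results) {
  arrange(as_tibble(results), .data$adjusted_p, .data$p_value,
          .data$dna_gene, .data$rna_gene)
}

#' Partition significant pairs into concordant and discordant
#'
#' @param results A `gene_pair_screen` tibble (or any tibble carrying
#'   `adjusted_p` and `is_concordant_pair`).
#' @param alpha Adjusted-p threshold; pairs with `adjusted_p < alpha` are
#'   significant.
#' @return A list of class `screen_partition`: `concordant` and `discordant`
#'   tibbles of significant pairs (ranked by [rank_pairs()]) and `counts`, a
#'   one-row tibble with `n_pairs`, `n_significant`, `n_concordant`,
#'   `n_discordant`.
#' @export
partition_significant <- function(results, alpha = attr(results, "alpha") %||% 0.05) {
  check_required_columns(results, c("adjusted_p", "is_concordant_pair"),
                         "screen results")
  sig <- rank_pairs(filter(as_tibble(results), .data$adjusted_p < alpha))
  structure(list(
    concordant = filter(sig, .data$is_concordant_pair),
    discordant = filter(sig, !.data$is_concordant_pair),
    counts = tibble(
      n_pairs = nrow(results),
      n_significant = nrow(sig),
      n_concordant = sum(sig$is_concordant_pair),
      n_discordant = sum(!sig$is_concordant_pair),
      alpha = alpha
    )
  ), class = "screen_partition")
}

#' @export
print.screen_partition <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(
    "<screen_partition> %d of %d pairs significant at adjusted p < %g (%d concordant, %d discordant)\n",
    ct$n_significant, ct$n_pairs, ct$alpha, ct$n_concordant, ct$n_discordant))
  invisible(x)
}

#' @rdname run_screen
#' @param x A `gene_pair_screen` object.
#' @param ... Unused.
#' @export
tidy.gene_pair_screen <- function(x, ...) as_tibble(x)

#' @rdname run_screen
#' @export
glance.gene_pair_screen <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble(
    n_pairs = nrow(x),
    n_dna_genes = dplyr::n_distinct(x$dna_gene),
    n_rna_genes = dplyr::n_distinct(x$rna_gene),
    n_significant = sum(x$adjusted_p < alpha),
    n_concordant_significant = sum(x$adjusted_p < alpha & x$is_concordant_pair),
    alpha = alpha,
    n_patients = attr(x, "n_patients") %||% NA_integer_
  )
}

#' Write screen results to a TSV file
#'
#' @param results A `gene_pair_screen` tibble.
#' @param path Output path (`pairs.tsv`).
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, na = "NA", progress = FALSE)
  invisible(path)
}
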