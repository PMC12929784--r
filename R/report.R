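#' Run the full concordance analysis and assemble a report
#'
#' One-shot pipeline driver: cohort summary, concordant-event detection with
#' its copy-number/expression correlation and purity comparison, the
#' exhaustive DNA-gene x RNA-gene Fisher/Benjamini-Hochberg screen with its
#' concordant/discordant partition, optional pathway over-representation and
#' transcription-factor annotation with the weighted association network,
#' and the TTB survival analysis with the PD-L1 comparison. With `out_dir`
#' set, every stage's table is written as TSV alongside a JSON run manifest
#' (tool version, parameters, per-file MD5 checksum and row count); outputs
#' are deterministic functions of the inputs, so re-running reproduces them
#' byte for byte.
#'
#' @param x A [cohort()] object.
#' @param gene_sets Optional `gene_set_collection` (see [read_gmt()]); size
#'   filters are applied here.
#' @param tf_edges Optional regulatory edge list (see [read_trrust()]).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param ttb_breaks TTB stratum bounds (default `c(2, 5)`).
#' @param treated_only Restrict survival analysis to treated patients.
#' @param min_set_size,max_set_size_exclusive,min_overlap Enrichment filters,
#'   as in [filter_gene_sets()] and [enrich_overrepresentation()].
#' @param out_dir Optional output directory for stage TSVs and the manifest.
#' @return Object of class `concordance_report`: a list with `summary`,
#'   `concordance`, `cn_expression`, `purity_test`, `screen`, `partition`,
#'   `enrichment` (or `NULL`), `tf_pairs` (or `NULL`), `network`,
#'   `survival`, `pdl1_test` and `parameters`.
#' @export
run_report <- function(x, gene_sets = NULL, tf_edges = NULL, alpha = 0.05,
                       ttb_breaks = c(2, 5), treated_only = TRUE,
                       min_set_size = 10, max_set_size_exclusive = 250,
                       min_overlap = 10, out_dir = NULL) {
  stopifnot(inherits(x, "cohort"))
  summary <- cohort_summary(x)
  concordance <- detect_concordant_events(x)
  cn_expression <- cn_expression_correlation(concordance)
  purity_test <- purity_concordance_test(x, concordance)

  screen <- run_screen(x, alpha = alpha)
  partition <- partition_significant(screen, alpha = alpha)
  sig_pairs <- bind_rows(partition$concordant, partition$discordant)

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    filtered <- filter_gene_sets(gene_sets, min_set_size,
                                 max_size_exclusive = max_set_size_exclusive)
    if (nrow(filtered) && nrow(sig_pairs)) {
      enrichment <- enrich_overrepresentation(
        build_query_from_pairs(sig_pairs), filtered,
        min_overlap = min_overlap, alpha = alpha
      )
    }
  }
  tf_pairs <- NULL
  if (!is.null(tf_edges) && nrow(sig_pairs)) {
    tf_pairs <- annotate_tf_target_pairs(sig_pairs, tf_edges)
  }
  network <- if (nrow(sig_pairs)) {
    build_association_network(sig_pairs, tf_pairs)
  } else NULL

  survival <- ttb_survival(x, breaks = ttb_breaks, treated_only = treated_only)
  pdl1_test <- ttb_by_pdl1_test(x)

  report <- structure(list(
    summary = summary, concordance = concordance,
    cn_expression = cn_expression, purity_test = purity_test,
    screen = screen, partition = partition, enrichment = enrichment,
    tf_pairs = tf_pairs, network = network, survival = survival,
    pdl1_test = pdl1_test,
    parameters = list(alpha = alpha, ttb_breaks = sort(as.integer(ttb_breaks)),
                      treated_only = treated_only, min_set_size = min_set_size,
                      max_set_size_exclusive = max_set_size_exclusive,
                      min_overlap = min_overlap)
  ), class = "concordance_report")
  if (!is.null(out_dir)) write_report_outputs(report, out_dir)
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- x$summary
  ct <- x$partition$counts
  cat("== DNA-RNA concordance report ==\n")
  cat(sprintf("Cohort: %d patients; %d unique DNA genes, %d unique RNA genes\n",
              s$n_patients, s$n_dna_genes, s$n_rna_genes))
  g <- glance(x$concordance)
  cat(sprintf("Concordant events: %d events in %d patients (%d genes)\n",
              g$n_events, g$n_patients_with_events, g$n_genes_involved))
  if (x$cn_expression$status == "ok") {
    cat(sprintf("  copy-number vs expression Spearman rho = %.2f (n = %d)\n",
                x$cn_expression$spearman_rho, x$cn_expression$n_events_used))
  }
  if (x$purity_test$status == "ok") {
    cat(sprintf("  purity, concordant vs not: Mann-Whitney p = %.3g\n",
                x$purity_test$p_value))
  }
  cat(sprintf("Screen: %d pairs; %d significant at adjusted p < %g (%d concordant, %d discordant)\n",
              ct$n_pairs, ct$n_significant, ct$alpha, ct$n_concordant,
              ct$n_discordant))
  top <- head(rank_pairs(bind_rows(x$partition$concordant, x$partition$discordant)), 3)
  if (nrow(top)) {
    cat("  top pairs: ",
        paste(sprintf("%s-%s (adj p %.2g)", top$dna_gene, top$rna_gene,
                      top$adjusted_p), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$enrichment) && nrow(x$enrichment)) {
    cat(sprintf("Enrichment: %d gene set(s) reported; top: %s (adj p %.2g)\n",
                nrow(x$enrichment), x$enrichment$set_name[1],
                x$enrichment$adjusted_p[1]))
  }
  if (!is.null(x$tf_pairs)) {
    cat(sprintf("TF-target pairs among significant pairs: %d\n", nrow(x$tf_pairs)))
  }
  print(x$survival)
  if (x$pdl1_test$status == "ok") {
    cat(sprintf("TTB by PD-L1 (negative vs positive): Mann-Whitney p = %.3g\n",
                x$pdl1_test$p_value))
  }
  invisible(x)
}

#' Write the stage outputs and run manifest of a report
#'
#' @param report A `concordance_report` from [run_report()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_report_outputs <- function(report, out_dir) {
  stopifnot(inherits(report, "concordance_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$events <- write_events(report$concordance, file.path(out_dir, "events.tsv"))
  paths$pairs <- write_pairs(report$screen, file.path(out_dir, "pairs.tsv"))
  if (!is.null(report$enrichment)) {
    enr <- mutate(report$enrichment,
                  overlap_genes = vapply(.data$overlap_genes, paste,
                                         character(1), collapse = ";"))
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"), na = "NA",
                     progress = FALSE)
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
  }
  if (!is.null(report$network)) {
    paths$network_edges <- write_network_edges(
      report$network, file.path(out_dir, "network_edges.tsv"))
  }
  paths$survival <- write_survival(report$survival, file.path(out_dir, "survival.tsv"))
  paths$km_curves <- write_km_curves(report$survival, file.path(out_dir, "km_curves.tsv"))

  manifest <- list(
    tool = "rnaconcord",
    version = as.character(utils::packageVersion("rnaconcord")),
    parameters = report$parameters,
    outputs = lapply(paths, function(p) {
      list(path = basename(p),
           md5 = unname(tools::md5sum(p)),
           n_rows = length(readLines(p, warn = FALSE)) - 1L)
    })
  )
  # atomic write: temp file in the same directory, then rename
  tmp <- tempfile("manifest", tmpdir = out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
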