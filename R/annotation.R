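#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`
#' (ignored), then member genes. Members are normalized with
#' [normalize_gene_symbol()] and deduplicated within a set.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble of class `gene_set_collection` with `set_name`, `n_members`
#'   and a `members` list-column of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "rnaconcord_validation_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("empty GMT file: %s", path))
    return(new_gene_set_collection(tibble(
      set_name = character(), n_members = integer(), members = list()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1]),
          class = "rnaconcord_validation_error")
  }
  sets <- tibble(
    set_name = vapply(fields, `[[`, "", 1L),
    members = lapply(fields, function(f) unique(normalize_gene_symbol(f[-(1:2)])))
  )
  dup <- which(duplicated(sets$set_name))
  if (length(dup)) validation_error("duplicate gene-set name in GMT", rows = dup)
  new_gene_set_collection(mutate(sets, n_members = lengths(.data$members),
                                 .after = "set_name"))
}

new_gene_set_collection <- function(df) {
  structure(df, class = c("gene_set_collection", class(tibble())))
}

#' Size-filter a gene-set collection
#'
#' Keeps sets with at least `min_size` and fewer than `max_size_exclusive`
#' members (so a 250-member set is excluded at the defaults). Idempotent.
#'
#' @param sets A `gene_set_collection` (or tibble with a `members`
#'   list-column).
#' @param min_size Inclusive lower bound on set size (default 10).
#' @param max_size_exclusive Exclusive upper bound on set size (default 250).
#' @return The filtered collection.
#' @export
filter_gene_sets <- function(sets, min_size = 10, max_size_exclusive = 250) {
  check_required_columns(sets, c("set_name", "members"), "gene-set collection")
  sz <- lengths(sets$members)
  out <- sets[sz >= min_size & sz < max_size_exclusive, , drop = FALSE]
  new_gene_set_collection(as_tibble(out))
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric upper-tail test per gene set: with a universe of
#' `N` genes, `K` of which belong to the set, and a query of `n` genes, the
#' p-value is `P(X >= overlap)` for `X ~ Hypergeometric(N, K, n)`.
#' Benjamini-Hochberg adjustment is computed across *all* sets in the
#' supplied (already size-filtered) collection; the reported rows are then
#' restricted to sets with `overlap >= min_overlap` and `adjusted_p < alpha`,
#' sorted by adjusted p.
#'
#' The default universe is the union of members of the supplied collection —
#' self-contained, requiring no external gene catalog — and can be overridden.
#' Query genes outside the universe are dropped with a warning; set members
#' outside the universe are ignored in `K` and in overlaps.
#'
#' @param query Character vector of gene symbols (normalized internally).
#' @param sets A `gene_set_collection`, typically from [read_gmt()] then
#'   [filter_gene_sets()].
#' @param universe Optional character vector of background genes.
#' @param min_overlap Minimum query/set overlap for a set to be reported
#'   (default 10).
#' @param alpha Adjusted-p threshold for reporting (default 0.05).
#' @param report_all If `TRUE`, return every tested set with a `reported`
#'   flag instead of only the passing rows.
#' @return Tibble with `set_name`, `set_size` (within the universe),
#'   `overlap`, `overlap_genes` (list-column), `p_value`, `adjusted_p` and,
#'   when `report_all = TRUE`, `reported`.
#' @export
enrich_overrepresentation <- function(query, sets, universe = NULL,
                                      min_overlap = 10, alpha = 0.05,
                                      report_all = FALSE) {
  check_required_columns(sets, c("set_name", "members"), "gene-set collection")
  if (!nrow(sets)) abort("empty gene-set collection")
  query <- unique(normalize_gene_symbol(query))
  universe <- unique(normalize_gene_symbol(
    universe %||% unlist(sets$members, use.names = FALSE)
  ))
  if (!length(universe)) abort("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- setdiff(query, outside)
  }
  if (!length(query)) abort("empty query after restricting to the universe")

  n_univ <- length(universe)
  n_query <- length(query)
  res <- sets |>
    as_tibble() |>
    mutate(
      members_in_universe = lapply(.data$members, intersect, universe),
      set_size = lengths(.data$members_in_universe),
      overlap_genes = lapply(.data$members_in_universe, intersect, query),
      overlap = lengths(.data$overlap_genes),
      p_value = stats::phyper(.data$overlap - 1, .data$set_size,
                              n_univ - .data$set_size, n_query,
                              lower.tail = FALSE),
      adjusted_p = bh_adjust(.data$p_value),
      reported = .data$overlap >= min_overlap & .data$adjusted_p < alpha
    ) |>
    select("set_name", "set_size", "overlap", "overlap_genes",
           "p_value", "adjusted_p", "reported") |>
    arrange(.data$adjusted_p, .data$p_value, .data$set_name)
  if (report_all) res else select(filter(res, .data$reported), -"reported")
}

#' Query gene list from significant pairs
#'
#' The union of DNA-side and RNA-side genes over a list of significant gene
#' pairs — the query used for pathway over-representation.
#'
#' @param pairs Tibble with `dna_gene` and `rna_gene` columns (e.g. the
#'   significant rows of a [run_screen()] result, or a
#'   [partition_significant()] component bound back together).
#' @return Sorted character vector of unique gene symbols.
#' @export
build_query_from_pairs <- function(pairs) {
  check_required_columns(pairs, c("dna_gene", "rna_gene"), "pair table")
  sort(unique(c(pairs$dna_gene, pairs$rna_gene)))
}

#' Read a TRRUST-style transcription-factor edge list
#'
#' Tab-separated, no header: `tf`, `target`, `mode` (`Activation`,
#' `Repression` or `Unknown`, case-insensitive), `references`. Symbols are
#' normalized; duplicate (tf, target) rows with different modes are kept.
#'
#' @param path Path to the edge-list file.
#' @return Tibble with `tf`, `target`, `mode` (one of `activation`,
#'   `repression`, `unknown`).
#' @export
read_trrust <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "rnaconcord_validation_error")
  }
  df <- readr::read_tsv(path, col_names = c("tf", "target", "mode", "references"),
                        col_types = "cccc", na = c("", "NA"), progress = FALSE)
  if (!nrow(df)) {
    warn(sprintf("empty regulatory edge list: %s", path))
    return(tibble(tf = character(), target = character(), mode = character()))
  }
  bad <- which(is.na(df$tf) | is.na(df$target))
  if (length(bad)) validation_error("edge with missing tf or target", rows = bad, file = path)
  mode <- tolower(trimws(df$mode))
  mode[is.na(mode) | !mode %in% c("activation", "repression")] <- "unknown"
  tibble(
    tf = normalize_gene_symbol(df$tf),
    target = normalize_gene_symbol(df$target),
    mode = mode
  ) |> distinct()
}

#' Annotate gene pairs as transcription-factor/target relations
#'
#' A pair is annotated when its DNA-side gene is a known transcription factor
#' and its RNA-side gene one of that factor's targets — an exact directed
#' match `(dna_gene = tf, rna_gene = target)`; the reverse orientation does
#' not match. Multiple regulatory modes for the same edge are collapsed with
#' `";"`.
#'
#' @param pairs Tibble with `dna_gene` and `rna_gene` columns.
#' @param edges Regulatory edge list from [read_trrust()] (columns `tf`,
#'   `target`, `mode`).
#' @return The subset of `pairs` that matches, with a `mode` column appended.
#' @export
annotate_tf_target_pairs <- function(pairs, edges) {
  check_required_columns(pairs, c("dna_gene", "rna_gene"), "pair table")
  check_required_columns(edges, c("tf", "target", "mode"), "edge list")
  modes <- edges |>
    group_by(.data$tf, .data$target) |>
    summarise(mode = paste(sort(unique(.data$mode)), collapse = ";"),
              .groups = "drop")
  inner_join(as_tibble(pairs), modes,
             by = c(dna_gene = "tf", rna_gene = "target"))
}

#' Build the weighted DNA-RNA association network
#'
#' Nodes are genes; genes with genomic alterations are the edge sources and
#' genes with altered expression the edge targets (a gene present on both
#' sides is tagged `both`). Each significant pair contributes one directed
#' edge weighted `-log10(adjusted p)`; an adjusted p of exactly zero
#' (floating underflow) is replaced by the smallest positive double so that
#' weights stay finite, and the substitution is messaged. Edges matching a
#' transcription-factor/target relation are flagged, which splits the
#' network into a TF-target subnetwork and the remainder (see
#' [split_network()]).
#'
#' @param pairs Tibble of significant pairs with `dna_gene`, `rna_gene`,
#'   `adjusted_p`.
#' @param tf_pairs Optional output of [annotate_tf_target_pairs()] on the
#'   same pairs; `NULL` flags no edge.
#' @return Object of class `association_network`: list with `nodes`
#'   (`gene`, `role` in `dna_source`/`rna_target`/`both`) and `edges`
#'   (`source`, `target`, `weight`, `tf_target_flag`).
#' @export
build_association_network <- function(pairs, tf_pairs = NULL) {
  check_required_columns(pairs, c("dna_gene", "rna_gene", "adjusted_p"), "pair table")
  pairs <- as_tibble(pairs)
  adj <- pairs$adjusted_p
  if (any(adj == 0)) {
    inform(sprintf("%d adjusted p-value(s) of 0 replaced by %.3g before -log10",
                   sum(adj == 0), .Machine$double.xmin))
    adj[adj == 0] <- .Machine$double.xmin
  }
  tf_key <- if (!is.null(tf_pairs) && nrow(tf_pairs)) {
    paste(tf_pairs$dna_gene, tf_pairs$rna_gene)
  } else character()
  edges <- tibble(
    source = pairs$dna_gene, target = pairs$rna_gene,
    weight = -log10(adj),
    tf_target_flag = paste(pairs$dna_gene, pairs$rna_gene) %in% tf_key
  )
  nodes <- tibble(
    gene = unique(c(edges$source, edges$target)),
    role = dplyr::case_when(
      .data$gene %in% edges$source & .data$gene %in% edges$target ~ "both",
      .data$gene %in% edges$source ~ "dna_source",
      TRUE ~ "rna_target"
    )
  ) |> arrange(.data$gene)
  structure(list(nodes = nodes, edges = edges), class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d nodes, %d edges (%d TF-target)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$tf_target_flag)))
  invisible(x)
}

#' Split an association network into TF-target subnetwork and remainder
#'
#' @param network An `association_network`.
#' @return List with `tf_target` and `other` edge tibbles; the two are
#'   disjoint and their union is the full edge set.
#' @export
split_network <- function(network) {
  stopifnot(inherits(network, "association_network"))
  list(
    tf_target = filter(network$edges, .data$tf_target_flag),
    other = filter(network$edges, !.data$tf_target_flag)
  )
}

#' Export an association network
#'
#' `write_network_edges()` writes the edge table as TSV; `export_network_dot()`
#' writes a Graphviz DOT file (directed, edge `penwidth` proportional to the
#' association weight).
#'
#' @param network An `association_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "association_network"))
  readr::write_tsv(network$edges, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
export_network_dot <- function(network, path) {
  stopifnot(inherits(network, "association_network"))
  e <- network$edges
  w <- e$weight / max(e$weight, 1)
  lines <- c(
    "digraph dna_rna_association {",
    "  rankdir=LR;",
    sprintf('  "%s" -> "%s" [penwidth=%.2f, style=%s];',
            e$source, e$target, 0.5 + 3 * w,
            ifelse(e$tf_target_flag, "bold", "solid")),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
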