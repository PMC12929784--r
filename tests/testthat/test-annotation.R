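test_that("GMT parsing: format, dedup, and failure modes", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tTP53\tKRAS",
               "SETB\tdesc\tmyc\tMYC\tEGFR"), path)
  gs <- read_gmt(path)
  expect_identical(gs$set_name, c("SETA", "SETB"))
  expect_identical(gs$members[[1]], c("TP53", "KRAS"))
  # lower-case duplicate collapses after normalization
  expect_identical(gs$members[[2]], c("MYC", "EGFR"))

  writeLines("ONLY\tTWO", path)
  expect_error(read_gmt(path), "line 1")

  writeLines(character(), path)
  expect_warning(empty <- read_gmt(path), "empty")
  expect_identical(nrow(empty), 0L)

  writeLines(c("DUP\td\tA\tB\tC", "DUP\td\tD\tE\tF"), path)
  expect_error(read_gmt(path), "duplicate")
})

test_that("size filter keeps [10, 250) and is idempotent", {
  sets <- tibble::tibble(
    set_name = c("s9", "s10", "s249", "s250"),
    members = lapply(c(9, 10, 249, 250), function(k) sprintf("G%03d", 1:k))
  )
  f <- filter_gene_sets(sets)
  expect_identical(f$set_name, c("s10", "s249"))
  expect_identical(filter_gene_sets(f)$set_name, f$set_name)
})

test_that("over-representation p-values are closed-form hypergeometric", {
  universe <- sprintf("U%02d", 1:20)
  sets <- tibble::tibble(set_name = "S", members = list(universe[1:10]))
  res <- enrich_overrepresentation(universe[1:10], sets, universe = universe,
                                   min_overlap = 10, alpha = 1)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$overlap, 10L)

  # query = universe saturates every set: p = 1
  res2 <- enrich_overrepresentation(universe, sets, universe = universe,
                                    min_overlap = 1, alpha = 1, report_all = TRUE)
  expect_equal(res2$p_value, 1)

  # disjoint query is filtered out by min_overlap
  sets2 <- dplyr::bind_rows(sets,
                            tibble::tibble(set_name = "T", members = list(universe[11:20])))
  res3 <- enrich_overrepresentation(universe[1:10], sets2, universe = universe,
                                    min_overlap = 1, alpha = 1, report_all = TRUE)
  expect_identical(res3$overlap[res3$set_name == "T"], 0L)
  expect_false(res3$reported[res3$set_name == "T"])

  # query genes outside the universe are dropped with a warning
  expect_warning(
    enrich_overrepresentation(c(universe[1:10], "ALIEN"), sets,
                              universe = universe, min_overlap = 1, alpha = 1),
    "outside the universe")
  expect_error(
    suppressWarnings(enrich_overrepresentation("ALIEN", sets, universe = universe)),
    "empty query")
})

test_that("enrichment matches enumeration for small universes", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n_univ <- sample(10:30, 1)
      universe <- sprintf("U%02d", seq_len(n_univ))
      sets <- tibble::tibble(
        set_name = c("A", "B"),
        members = list(sample(universe, sample(3:n_univ, 1)),
                       sample(universe, sample(3:n_univ, 1))))
      query <- sample(universe, sample(2:n_univ, 1))
      res <- enrich_overrepresentation(query, sets, universe = universe,
                                       min_overlap = 0, alpha = 1,
                                       report_all = TRUE)
      for (j in seq_len(nrow(res))) {
        k_set <- length(intersect(sets$members[[match(res$set_name[j], sets$set_name)]],
                                  universe))
        expect_equal(res$p_value[j],
                     oracle_hyper_upper(n_univ, k_set, length(query), res$overlap[j]),
                     tolerance = 1e-12)
      }
      expect_equal(sort(res$adjusted_p), sort(oracle_bh(res$p_value)),
                   tolerance = 1e-12)
    }
  })
})

test_that("query building is the union over significant pairs", {
  pairs <- tibble::tibble(dna_gene = c("TP53", "KRAS"),
                          rna_gene = c("VEGFA", "VEGFA"))
  expect_identical(build_query_from_pairs(pairs), c("KRAS", "TP53", "VEGFA"))
  expect_identical(build_query_from_pairs(pairs[0, ]), character())

  withr::with_seed(7, {
    big <- tibble::tibble(dna_gene = sample(LETTERS, 123, replace = TRUE),
                          rna_gene = sample(letters, 123, replace = TRUE))
  })
  expect_identical(build_query_from_pairs(big),
                   sort(unique(c(big$dna_gene, big$rna_gene))))
})

test_that("TF-target annotation is an exact directed match", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trrust_fixture(path, data.frame(
    tf = c("TP53", "MYC", "TP53"), target = c("VEGFA", "CDK4", "VEGFA"),
    mode = c("Repression", "Activation", "Unknown")))
  edges <- read_trrust(path)
  expect_setequal(unique(edges$mode), c("repression", "activation", "unknown"))

  pairs <- tibble::tibble(dna_gene = c("TP53", "VEGFA", "KRAS"),
                          rna_gene = c("VEGFA", "TP53", "MYC"),
                          adjusted_p = c(0.01, 0.01, 0.04))
  ann <- annotate_tf_target_pairs(pairs, edges)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$dna_gene, "TP53")   # (VEGFA, TP53) must NOT match
  expect_identical(ann$mode, "repression;unknown")
})

test_that("random TF annotation equals a brute-force join", {
  withr::with_seed(13, {
    pairs <- tibble::tibble(
      dna_gene = sample(LETTERS[1:8], 30, replace = TRUE),
      rna_gene = sample(LETTERS[1:8], 30, replace = TRUE)) |>
      dplyr::distinct()
    edges <- tibble::tibble(
      tf = sample(LETTERS[1:8], 12, replace = TRUE),
      target = sample(LETTERS[1:8], 12, replace = TRUE),
      mode = sample(c("activation", "repression"), 12, replace = TRUE)) |>
      dplyr::distinct(tf, target, .keep_all = TRUE)
  })
  ann <- annotate_tf_target_pairs(pairs, edges)
  brute <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(edges))) {
      if (pairs$dna_gene[i] == edges$tf[j] && pairs$rna_gene[i] == edges$target[j]) {
        brute[i] <- TRUE
      }
    }
  }
  expect_identical(sort(paste(ann$dna_gene, ann$rna_gene)),
                   sort(paste(pairs$dna_gene, pairs$rna_gene)[brute]))
})

test_that("association network edges are in bijection with significant pairs", {
  pairs <- tibble::tibble(
    dna_gene = c("TP53", "KRAS", "APC"),
    rna_gene = c("VEGFA", "VEGFA", "MYC"),
    adjusted_p = c(0.001, 0.05, 0.02))
  tf <- tibble::tibble(dna_gene = "TP53", rna_gene = "VEGFA", mode = "repression")
  net <- build_association_network(pairs, tf)
  expect_identical(nrow(net$edges), 3L)
  expect_equal(net$edges$weight[net$edges$source == "KRAS"], -log10(0.05))
  sp <- split_network(net)
  expect_identical(nrow(sp$tf_target), 1L)
  expect_identical(nrow(sp$other), 2L)
  expect_identical(nrow(sp$tf_target) + nrow(sp$other), nrow(pairs))

  # node roles
  expect_identical(net$nodes$role[net$nodes$gene == "TP53"], "dna_source")
  expect_identical(net$nodes$role[net$nodes$gene == "VEGFA"], "rna_target")

  # underflowed adjusted p maps to a finite weight, with a message
  pz <- dplyr::mutate(pairs, adjusted_p = c(0, 0.01, 0.02))
  expect_message(netz <- build_association_network(pz), "replaced")
  expect_true(all(is.finite(netz$edges$weight)))

  # a gene on both sides is tagged "both"
  both <- build_association_network(
    tibble::tibble(dna_gene = c("TP53", "MYC"), rna_gene = c("MYC", "EGFR"),
                   adjusted_p = 0.01))
  expect_identical(both$nodes$role[both$nodes$gene == "MYC"], "both")
})

test_that("network export writes edge TSV and Graphviz DOT", {
  net <- build_association_network(
    tibble::tibble(dna_gene = "TP53", rna_gene = "VEGFA", adjusted_p = 0.01))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network_edges(net, tsv)
  expect_identical(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 1L)
  export_network_dot(net, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("TP53.*->.*VEGFA.*penwidth", txt)))
})
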