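#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object (step curve with censoring ticks).
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1), as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(df, .data$n_censor > 0), shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot overall survival stratified by tumor transcriptional burden
#'
#' @param object A `ttb_survival` from [ttb_survival()].
#' @param ... Unused.
#' @return A ggplot object: one Kaplan-Meier step curve per TTB stratum,
#'   annotated with the log-rank p-value.
#' @export
autoplot.ttb_survival <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$stratum) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, survival = 1), .x)) |>
    ungroup()
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                            colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Overall survival (months)", y = "Survival probability",
                  colour = "TTB stratum") +
    ggplot2::theme_minimal()
  if (!is.null(object$logrank)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("log-rank p = %.3g", object$logrank$p_value))
  }
  p
}

#' Plot the alteration-class breakdown of concordant events
#'
#' @param object A `concordance_summary` from [detect_concordant_events()].
#' @param ... Unused.
#' @return A ggplot bar chart of event counts by primary alteration class.
#' @export
autoplot.concordance_summary <- function(object, ...) {
  bd <- event_class_breakdown(object)
  ggplot2::ggplot(bd, ggplot2::aes(x = stats::reorder(.data$primary_class, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Primary alteration class", y = "Concordant events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the most significant pairs of a screen
#'
#' @param object A `gene_pair_screen` from [run_screen()].
#' @param n_top Number of top-ranked pairs to show (default 20).
#' @param ... Unused.
#' @return A ggplot lollipop chart of `-log10(adjusted p)` for the top
#'   pairs, concordant pairs highlighted.
#' @export
autoplot.gene_pair_screen <- function(object, n_top = 20, ...) {
  top <- head(rank_pairs(object), n_top) |>
    mutate(
      pair = paste(.data$dna_gene, .data$rna_gene, sep = " → "),
      neg_log10_adj_p = -log10(pmax(.data$adjusted_p, .Machine$double.xmin))
    )
  ggplot2::ggplot(top, ggplot2::aes(x = .data$neg_log10_adj_p,
                                    y = stats::reorder(.data$pair, .data$neg_log10_adj_p),
                                    colour = .data$is_concordant_pair)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(.data$pair, .data$neg_log10_adj_p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10]("adjusted p")), y = NULL,
                  colour = "Concordant pair") +
    ggplot2::theme_minimal()
}

#' Plot a DNA-RNA association network
#'
#' Bipartite layout: DNA-side genes (edge sources) on the left, RNA-side
#' genes (edge targets) on the right; line width encodes the association
#' weight `-log10(adjusted p)` and TF-target edges are drawn solid.
#'
#' @param object An `association_network` from [build_association_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_network <- function(object, ...) {
  src <- sort(unique(object$edges$source))
  tgt <- sort(unique(object$edges$target))
  pos <- bind_rows(
    tibble(gene = src, x = 0, y = seq_along(src) / max(1, length(src))),
    tibble(gene = tgt, x = 1, y = seq_along(tgt) / max(1, length(tgt)))
  )
  e <- object$edges |>
    left_join(rename(pos[pos$x == 0, ], x0 = "x", y0 = "y"), by = c(source = "gene")) |>
    left_join(rename(pos[pos$x == 1, ], x1 = "x", y1 = "y"), by = c(target = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$weight, linetype = !.data$tf_target_flag),
      alpha = 0.6, show.legend = c(linewidth = TRUE, linetype = FALSE)) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
                       hjust = ifelse(pos$x == 0, 1.1, -0.1), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::xlim(-0.4, 1.4) +
    ggplot2::labs(linewidth = expression(-log[10]("adjusted p"))) +
    ggplot2::theme_void()
}
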