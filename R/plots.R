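#' Plot rarefaction curves
#'
#' One line per sample: mean observed richness against subsampling depth.
#'
#' @param curves tibble from [rarefaction_curve()].
#' @param index `"richness"` or `"shannon"`.
#' @return a ggplot object.
#' @export
plot_rarefaction <- function(curves, index = c("richness", "shannon")) {
  index <- match.arg(index)
  y <- if (index == "richness") "mean_s_obs" else "mean_shannon"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$depth, y = .data[[y]],
                                       colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads subsampled",
                  y = if (index == "richness") "mean observed OTUs"
                      else "mean Shannon index",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' Plot degree-of-enrichment ratios
#'
#' Per-species enrichment ratio at the isolation day on a log10 scale,
#' with the enriched / not-enriched boundary at ratio 1 marked.
#'
#' @param calls an `enrichment_calls` object from [classify_enrichment()].
#' @return a ggplot object.
#' @export
plot_enrichment <- function(calls) {
  stopifnot(inherits(calls, "enrichment_calls"))
  df <- calls$calls |> filter(.data$isolation_day > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$isolate_id, .data$ratio),
                                   y = .data$ratio, fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "(abundance at isolation + 1) / (day-0 abundance + 1)",
                  fill = "enriched") +
    ggplot2::theme_minimal()
}

#' Plot activity ratios over the enrichment time course
#'
#' Boxplots of per-taxon log10 RNA:DNA ratios by day (one panel per
#' source), with the active/dormant boundary (ratio 1, i.e. log10 = 0)
#' dashed.
#'
#' @param records activity table from [aggregate_activity()].
#' @param taxa optional subset of taxa to show.
#' @return a ggplot object.
#' @export
plot_activity <- function(records, taxa = NULL) {
  df <- records |> filter(.data$present)
  if (!is.null(taxa)) df <- df |> filter(.data$taxon %in% taxa)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$day), y = .data$log10_ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~source) +
    ggplot2::labs(x = "enrichment day", y = "log10 (16S rRNA + 1) / (16S rRNA gene + 1)") +
    ggplot2::theme_minimal()
}

#' @describeIn build_network network drawing (Fruchterman-Reingold
#'   layout; edge colour by sign).
#' @param object a `co_network`.
#' @export
autoplot.co_network <- function(object, ...) {
  g <- as_igraph(object, drop_isolated = TRUE)
  if (igraph::vcount(g) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  xy <- withr::with_seed(1L, igraph::layout_with_fr(g))
  nodes <- tibble(feature_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    left_join(nodes |> rename(feature_a = "feature_id", xa = "x", ya = "y"),
              by = "feature_a") |>
    left_join(nodes |> rename(feature_b = "feature_id", xb = "x", yb = "y"),
              by = "feature_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       colour = .data$sign),
                          alpha = 0.7) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#b2182b")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "association")
}
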