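#' Prevalence and abundance filter for network inference
#'
#' Keeps features observed in enough samples for a meaningful
#' correlation: a feature is retained when its number of zero-count
#' samples is at most `max_zeros` *and* its total reads exceed
#' `majority`. Feature order is preserved. Removing every feature is a
#' warning (an empty table is returned), not an error.
#'
#' @param counts wide count tibble (>= 3 samples).
#' @param max_zeros maximum zero occurrences per feature (default 2).
#' @param majority total-abundance floor: features must have total reads
#'   strictly greater than this (default 1).
#' @return filtered wide count tibble.
#' @export
filter_features <- function(counts, max_zeros = 2, majority = 1) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 3) abort("need at least 3 samples to filter for correlation")
  keep <- rowSums(m == 0) <= max_zeros & rowSums(m) > majority
  if (!any(keep)) warn("all features removed by the zero/abundance filter")
  counts[keep, , drop = FALSE]
}

#' Build an OTU co-occurrence network
#'
#' Log10-transforms the counts treating zeros as missing (blank), computes
#' Pearson correlations between features over pairwise-complete samples,
#' and keeps edges with `|r| >= threshold` supported by at least
#' `min_pairs` complete sample pairs. Pairs with fewer complete pairs are
#' skipped and recorded, not errors. The graph is undirected; each edge
#' is stored once with its endpoints in lexicographic order.
#'
#' @param counts wide count tibble, already passed through
#'   [filter_features()].
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @param min_pairs minimum complete (both nonzero) sample pairs per edge
#'   (default 9); inert on tables filtered at `max_zeros = 2` over 15
#'   samples, where every pair has at least 11.
#' @return object of class `co_network`: list with `nodes` (feature_id,
#'   n_samples_nonzero), `edges` (feature_a, feature_b, r, sign,
#'   n_pairs), `skipped` (pairs under `min_pairs`) and `params`.
#' @export
build_network <- function(counts, threshold = 0.7, min_pairs = 9) {
  m <- as_count_matrix(counts)
  if (nrow(m) < 2) {
    return(structure(list(
      nodes = tibble(feature_id = rownames(m), n_samples_nonzero = rowSums(m > 0)),
      edges = empty_edges(), skipped = empty_edges()[0, 1:3],
      params = list(threshold = threshold, min_pairs = min_pairs)),
      class = "co_network"))
  }
  lm <- log10(m)
  lm[!is.finite(lm)] <- NA            # zeros kept blank
  x <- t(lm)                          # samples x features
  suppressWarnings(r <- cor(x, use = "pairwise.complete.obs", method = "pearson"))
  np <- crossprod(!is.na(x))          # complete pairs per feature pair
  ut <- which(upper.tri(r), arr.ind = TRUE)
  ids <- rownames(m)
  all_pairs <- tibble(feature_a = ids[ut[, 1]], feature_b = ids[ut[, 2]],
                      r = r[ut], n_pairs = as.integer(np[ut]))
  # lexicographic endpoint order
  swap <- all_pairs$feature_a > all_pairs$feature_b
  tmp <- all_pairs$feature_a[swap]
  all_pairs$feature_a[swap] <- all_pairs$feature_b[swap]
  all_pairs$feature_b[swap] <- tmp
  skipped <- all_pairs |> filter(.data$n_pairs < min_pairs) |>
    select("feature_a", "feature_b", "n_pairs")
  edges <- all_pairs |>
    filter(.data$n_pairs >= min_pairs, !is.na(.data$r),
           abs(.data$r) >= threshold) |>
    mutate(sign = ifelse(.data$r >= 0, "positive", "negative")) |>
    select("feature_a", "feature_b", "r", "sign", "n_pairs") |>
    arrange(.data$feature_a, .data$feature_b)
  structure(list(
    nodes = tibble(feature_id = ids, n_samples_nonzero = as.integer(rowSums(m > 0))),
    edges = edges, skipped = skipped,
    params = list(threshold = threshold, min_pairs = min_pairs)),
    class = "co_network")
}

empty_edges <- function() {
  tibble(feature_a = character(), feature_b = character(), r = double(),
         sign = character(), n_pairs = integer())
}

#' @export
print.co_network <- function(x, ...) {
  cat("<co_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges at |r| >= ", x$params$threshold,
      " (", sum(x$edges$sign == "positive"), " positive, ",
      sum(x$edges$sign == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' @describeIn build_network edge list as a tibble.
#' @param x a `co_network` object.
#' @param ... unused.
#' @export
tidy.co_network <- function(x, ...) x$edges

#' @describeIn build_network one-row summary of the network.
#' @export
glance.co_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_positive = sum(x$edges$sign == "positive"),
         n_negative = sum(x$edges$sign == "negative"),
         n_skipped_pairs = nrow(x$skipped),
         threshold = x$params$threshold)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param network a `co_network`.
#' @param drop_isolated drop nodes without edges (default FALSE).
#' @return an undirected `igraph` graph with edge attributes `r`, `sign`,
#'   `n_pairs`.
#' @export
as_igraph <- function(network, drop_isolated = FALSE) {
  stopifnot(inherits(network, "co_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  if (drop_isolated) g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  g
}

#' Write a co-occurrence network as GraphML
#'
#' @param network a `co_network`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Signed associations between taxonomic groups
#'
#' Collapses network edges to pairs of groups at a taxonomic rank and
#' reports, per group pair, the positive and negative edge counts and the
#' net sign (majority vote; a tie is `"mixed"`). Nodes without a lineage
#' are grouped as `"unclassified"`. Groups with no edges at all are
#' reported with zero counts and net sign `"none"`.
#'
#' @param network a `co_network`.
#' @param taxonomy tibble with `feature_id` and rank columns.
#' @param rank taxonomy column to group by (default `"family"`).
#' @return tibble: `group_a`, `group_b`, `n_pos`, `n_neg`, `net_sign`.
#' @export
group_associations <- function(network, taxonomy, rank = "family") {
  stopifnot(inherits(network, "co_network"))
  grp <- taxon_grouping(network$nodes$feature_id, character(), taxonomy, rank)
  ed <- network$edges |>
    left_join(grp |> rename(feature_a = "feature_id", group_a = "taxon"),
              by = "feature_a") |>
    left_join(grp |> rename(feature_b = "feature_id", group_b = "taxon"),
              by = "feature_b")
  swap <- ed$group_a > ed$group_b
  tmp <- ed$group_a[swap]; ed$group_a[swap] <- ed$group_b[swap]; ed$group_b[swap] <- tmp
  assoc <- ed |>
    group_by(.data$group_a, .data$group_b) |>
    summarise(n_pos = sum(.data$sign == "positive"),
              n_neg = sum(.data$sign == "negative"), .groups = "drop") |>
    mutate(net_sign = dplyr::case_when(
      .data$n_pos > .data$n_neg ~ "positive",
      .data$n_neg > .data$n_pos ~ "negative",
      TRUE ~ "mixed"))
  isolated <- setdiff(unique(grp$taxon), unique(c(assoc$group_a, assoc$group_b)))
  if (length(isolated)) {
    assoc <- bind_rows(assoc,
                       tibble(group_a = isolated, group_b = isolated,
                              n_pos = 0L, n_neg = 0L, net_sign = "none"))
  }
  assoc |> arrange(.data$group_a, .data$group_b)
}
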