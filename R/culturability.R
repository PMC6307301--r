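#' Degree-of-enrichment ratio
#'
#' `(a_t + 1) / (a_0 + 1)`: the pseudocounted ratio of a species'
#' (rarefied) read abundance at an enrichment stage to its day-0
#' abundance. The +1 guards against an initial abundance of zero — an
#' isolated species must have carried at least one cell in both the
#' initial and the isolation-stage sample. A ratio strictly greater than
#' 1 classifies the species as abundance-enriched; equal abundances give
#' exactly 1 and are *not* enriched.
#'
#' @param a_t non-negative reads at the enrichment stage.
#' @param a_0 non-negative reads at day 0 (same rarefaction depth).
#' @return numeric ratio(s), vectorized.
#' @examples
#' enrichment_ratio(251, 0)  # 252: strongly enriched
#' enrichment_ratio(0, 0)    # 1: not enriched
#' @export
enrichment_ratio <- function(a_t, a_0) {
  if (any(a_t < 0) || any(a_0 < 0)) abort("read counts must be non-negative")
  (a_t + 1) / (a_0 + 1)
}

#' Activity ratio from paired RNA/DNA libraries
#'
#' `(rna + 1) / (dna + 1)` for a taxon in paired 16S rRNA (RNA) and 16S
#' rRNA gene (DNA) libraries rarefied to a common per-molecule depth. A
#' ratio strictly greater than 1 classifies the taxon as metabolically
#' active; a ratio of 1 or less as dormant.
#'
#' @param rna non-negative 16S rRNA reads.
#' @param dna non-negative 16S rRNA gene reads.
#' @return numeric ratio(s), vectorized.
#' @export
activity_ratio <- function(rna, dna) {
  if (any(rna < 0) || any(dna < 0)) abort("read counts must be non-negative")
  (rna + 1) / (dna + 1)
}

#' Classify isolates as enriched or not at their isolation stage
#'
#' For every cultured species (isolate), compares its recruited read
#' abundance at each enrichment day with its day-0 abundance in the same
#' source, and flags it enriched when the ratio at its isolation day
#' exceeds 1. The headline summary — the fraction of isolations *not*
#' explained by abundance enrichment — is computed over species isolated
#' after enrichment (isolation day > 0); species isolated by direct
#' day-0 plating are excluded from that denominator.
#'
#' @param recruits a [recruit()] result or a long tibble
#'   `(isolate_id, sample_id, reads)` of recruited (rarefied) reads.
#' @param meta sample metadata (`sample_id`, `source`, `day`, optionally
#'   `molecule`; only DNA samples are used when present).
#' @param isolation tibble `(isolate_id, source, isolation_day)`.
#' @return object of class `enrichment_calls`: list with `records` (long:
#'   isolate_id, source, day, a_0, a_t, ratio, enriched), `calls` (one
#'   row per isolate: ratio and flag at the isolation day) and `summary`.
#' @export
classify_enrichment <- function(recruits, meta, isolation) {
  counts <- if (inherits(recruits, "recruitment")) recruits$counts else as_tibble(recruits)
  if (!all(c("isolate_id", "sample_id", "reads") %in% names(counts))) {
    abort("`recruits` must have columns isolate_id, sample_id, reads")
  }
  check_meta(meta, unique(counts$sample_id))
  if (!all(c("isolate_id", "source", "isolation_day") %in% names(isolation))) {
    abort("`isolation` needs columns isolate_id, source, isolation_day")
  }
  md <- meta
  if ("molecule" %in% names(md) && any(md$molecule == "DNA")) {
    md <- md |> filter(.data$molecule == "DNA")
  }
  long <- counts |>
    inner_join(md, by = "sample_id") |>
    inner_join(as_tibble(isolation), by = c("isolate_id", "source"))

  a0 <- long |> filter(.data$day == 0) |>
    select("isolate_id", "source", a_0 = "reads")
  missing0 <- setdiff(unique(long$isolate_id), a0$isolate_id)
  if (length(missing0)) {
    abort(paste0("no day-0 sample in the isolation source for: ",
                 paste(head(missing0, 5), collapse = ", ")))
  }
  records <- long |> filter(.data$day > 0) |>
    left_join(a0, by = c("isolate_id", "source")) |>
    mutate(a_t = .data$reads,
           ratio = enrichment_ratio(.data$a_t, .data$a_0),
           enriched = .data$ratio > 1) |>
    select("isolate_id", "source", "isolation_day", "day",
           "a_0", "a_t", "ratio", "enriched") |>
    arrange(.data$isolate_id, .data$day)
  calls <- bind_rows(
    records |> filter(.data$day == .data$isolation_day),
    # direct-plating isolates (day 0): ratio 1 by definition, kept in the
    # record set but excluded from the headline fraction
    a0 |> inner_join(as_tibble(isolation), by = c("isolate_id", "source")) |>
      filter(.data$isolation_day == 0) |>
      mutate(day = 0L, a_t = .data$a_0, ratio = 1, enriched = FALSE)
  ) |>
    select("isolate_id", "source", "isolation_day", "a_0", "a_t",
           "ratio", "enriched") |>
    arrange(.data$isolate_id)
  post <- calls |> filter(.data$isolation_day > 0)
  summary <- tibble(
    n_species = nrow(calls),
    n_post_enrichment = nrow(post),
    n_enriched = sum(post$enriched),
    n_not_enriched = sum(!post$enriched),
    frac_not_enriched = if (nrow(post)) mean(!post$enriched) else NA_real_)
  structure(list(records = records, calls = calls, summary = summary),
            class = "enrichment_calls")
}

#' @export
print.enrichment_calls <- function(x, ...) {
  s <- x$summary
  cat("<enrichment_calls> ", s$n_species, " species; of ", s$n_post_enrichment,
      " isolated after enrichment, ", s$n_not_enriched,
      " (", round(100 * s$frac_not_enriched, 1),
      "%) were not abundance-enriched\n", sep = "")
  invisible(x)
}

#' @describeIn classify_enrichment per-species, per-day ratio records.
#' @param x an `enrichment_calls` object.
#' @param ... unused.
#' @export
tidy.enrichment_calls <- function(x, ...) x$records

#' @describeIn classify_enrichment one-row headline summary.
#' @export
glance.enrichment_calls <- function(x, ...) x$summary

#' Aggregate paired RNA/DNA counts and call activity at a taxonomic rank
#'
#' Pairs RNA with DNA libraries by (source, day), sums reads within each
#' taxon at the requested rank (sum-then-ratio, so ratios are consistent
#' across ranks), and computes the pseudocounted activity ratio with its
#' log10 for plotting. `rank = "otu"` keeps per-feature ratios.
#'
#' @param rna_counts,dna_counts wide count tibbles for the RNA (16S rRNA)
#'   and DNA (16S rRNA gene) libraries, rarefied to a common per-molecule
#'   depth.
#' @param meta sample metadata covering both tables (`sample_id`,
#'   `source`, `day`, `molecule`).
#' @param taxonomy tibble mapping `feature_id` to rank columns (as from a
#'   simulated community); required unless `rank = "otu"`.
#' @param rank taxonomy column to aggregate at (`"otu"`, `"family"`,
#'   `"order"`, `"genus"`, ...).
#' @return tibble: `taxon`, `source`, `day`, `rna`, `dna`, `ratio`,
#'   `log10_ratio`, `active`, `present`.
#' @export
aggregate_activity <- function(rna_counts, dna_counts, meta,
                               taxonomy = NULL, rank = "otu") {
  check_counts(rna_counts); check_counts(dna_counts)
  check_meta(meta, c(names(rna_counts)[-1], names(dna_counts)[-1]))
  if (!"molecule" %in% names(meta)) abort("`meta` needs a molecule column")
  pairs_rna <- meta |> filter(.data$sample_id %in% names(rna_counts)[-1],
                              .data$molecule == "RNA")
  pairs_dna <- meta |> filter(.data$sample_id %in% names(dna_counts)[-1],
                              .data$molecule == "DNA")
  keys <- dplyr::full_join(
    pairs_dna |> select("source", "day", dna_sample = "sample_id"),
    pairs_rna |> select("source", "day", rna_sample = "sample_id"),
    by = c("source", "day"))
  if (any(is.na(keys$dna_sample)) || any(is.na(keys$rna_sample))) {
    abort("unpaired sample: every (source, day) needs one DNA and one RNA library")
  }
  grp <- taxon_grouping(rna_counts$feature_id, dna_counts$feature_id, taxonomy, rank)
  long <- function(counts, samples, value) {
    counts |>
      tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = value) |>
      filter(.data$sample_id %in% samples) |>
      left_join(grp, by = "feature_id")
  }
  rna_l <- long(rna_counts, keys$rna_sample, "rna") |>
    inner_join(keys |> select("source", "day", sample_id = "rna_sample"),
               by = "sample_id")
  dna_l <- long(dna_counts, keys$dna_sample, "dna") |>
    inner_join(keys |> select("source", "day", sample_id = "dna_sample"),
               by = "sample_id")
  dplyr::full_join(
    rna_l |> group_by(.data$taxon, .data$source, .data$day) |>
      summarise(rna = sum(.data$rna), .groups = "drop"),
    dna_l |> group_by(.data$taxon, .data$source, .data$day) |>
      summarise(dna = sum(.data$dna), .groups = "drop"),
    by = c("taxon", "source", "day")) |>
    mutate(rna = dplyr::coalesce(.data$rna, 0), dna = dplyr::coalesce(.data$dna, 0),
           ratio = activity_ratio(.data$rna, .data$dna),
           log10_ratio = log10(.data$ratio),
           active = .data$ratio > 1,
           present = .data$rna + .data$dna > 0) |>
    arrange(.data$taxon, .data$source, .data$day)
}

taxon_grouping <- function(ids_a, ids_b, taxonomy, rank) {
  ids <- union(ids_a, ids_b)
  if (identical(rank, "otu")) return(tibble(feature_id = ids, taxon = ids))
  if (is.null(taxonomy)) abort("a `taxonomy` table is required for rank != 'otu'")
  if (!rank %in% names(taxonomy)) {
    abort(paste0("rank '", rank, "' is not a taxonomy column"))
  }
  tibble(feature_id = ids) |>
    left_join(taxonomy |> select("feature_id", taxon = dplyr::all_of(rank)),
              by = "feature_id") |>
    mutate(taxon = dplyr::coalesce(.data$taxon, "unclassified"))
}

#' Proportion of active taxa per sample group
#'
#' Fraction of taxa present in a (source, day) pair — detected in the RNA
#' or the DNA library — whose activity ratio exceeds 1. The taxon-weighted
#' proportion is the primary statistic; a read-weighted version (weights =
#' rna + dna reads) is emitted alongside. Rows with source `"mean"` carry
#' the across-source average per day.
#'
#' @param records activity table from [aggregate_activity()].
#' @return tibble: `source`, `day`, `n_present`, `prop_active`,
#'   `prop_active_weighted`.
#' @export
proportion_active <- function(records) {
  need <- c("taxon", "source", "day", "rna", "dna", "active", "present")
  if (!all(need %in% names(records))) {
    abort("`records` must come from aggregate_activity()")
  }
  grp <- records |>
    filter(.data$present) |>
    group_by(.data$source, .data$day) |>
    summarise(n_present = n(),
              prop_active = mean(.data$active),
              prop_active_weighted =
                sum((.data$rna + .data$dna) * .data$active) /
                sum(.data$rna + .data$dna),
              .groups = "drop")
  if (nrow(grp) == 0) abort("no taxa present: proportion undefined")
  means <- grp |>
    group_by(.data$day) |>
    summarise(source = "mean", n_present = mean(.data$n_present),
              prop_active = mean(.data$prop_active),
              prop_active_weighted = mean(.data$prop_active_weighted),
              .groups = "drop") |>
    relocate("source")
  bind_rows(grp, means) |> arrange(.data$source, .data$day)
}
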