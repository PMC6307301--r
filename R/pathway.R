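#' Define a cofactor biosynthesis pathway
#'
#' A pathway is an ordered set of core synthesis gene symbols (all
#' required for de novo synthesis), optional salvage transporter symbols
#' (import routes open to auxotrophs), and an optional ligase that
#' attaches the finished cofactor.
#'
#' @param cofactor cofactor name.
#' @param core_genes ordered character vector of core synthesis gene
#'   symbols (non-empty, unique).
#' @param salvage_genes transporter gene symbols (may be empty).
#' @param ligase optional ligase symbol (informational; not scored).
#' @return object of class `pathway_def`.
#' @export
pathway_def <- function(cofactor, core_genes, salvage_genes = character(),
                        ligase = NULL) {
  if (length(core_genes) == 0) abort("core gene set must be non-empty")
  if (anyDuplicated(core_genes)) abort("core gene symbols must be unique")
  structure(list(cofactor = cofactor, core_genes = core_genes,
                 salvage_genes = salvage_genes, ligase = ligase),
            class = "pathway_def")
}

#' @export
print.pathway_def <- function(x, ...) {
  cat("<pathway_def> ", x$cofactor, ": ", length(x$core_genes),
      " core genes (", paste(x$core_genes, collapse = ", "), ")",
      if (length(x$salvage_genes)) paste0("; salvage: ",
                                          paste(x$salvage_genes, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Biotin biosynthesis pathway (default gene set)
#'
#' Core late-pathway genes bioC, bioH (pimeloyl precursor supply), bioF,
#' bioA, bioD, bioB, with the BioYM ECF-type transporter as the salvage
#' route and BirA as the biotin-protein ligase.
#'
#' @return a [pathway_def()].
#' @export
pathway_biotin <- function() {
  pathway_def("biotin",
              core_genes = c("bioC", "bioH", "bioF", "bioA", "bioD", "bioB"),
              salvage_genes = c("bioY", "bioM"),
              ligase = "birA")
}

#' Cobalamin (vitamin B12) biosynthesis pathway (editorial gene set)
#'
#' A ~20-symbol anaerobic corrinoid-ring and nucleotide-loop gene set
#' with the BtuBFCD salvage transporters. This default is an editorial
#' compilation of commonly used cobalamin marker genes, not a curated
#' reference; screens of real genomes should supply their own list via
#' [pathway_def()] or [read_pathways()].
#'
#' @return a [pathway_def()].
#' @export
pathway_cobalamin <- function() {
  pathway_def("cobalamin",
              core_genes = c("cysG", "cbiK", "cbiL", "cbiH", "cbiF", "cbiG",
                             "cbiD", "cbiJ", "cbiE", "cbiT", "cbiC", "cbiA",
                             "cbiP", "cbiB", "cobU", "cobT", "cobS", "cobC",
                             "cobD", "btuR"),
              salvage_genes = c("btuB", "btuF", "btuC", "btuD"))
}

#' Read pathway definitions from YAML
#'
#' Expected structure: a top-level map of cofactor names, each with
#' `core_genes` (required), `salvage_genes` and `ligase` (optional).
#'
#' @param path YAML file path.
#' @return named list of [pathway_def()] objects.
#' @export
read_pathways <- function(path) {
  y <- yaml::read_yaml(path)
  purrr::imap(y, function(v, nm) {
    pathway_def(nm, core_genes = as.character(v$core_genes),
                salvage_genes = as.character(v$salvage_genes %||% character()),
                ligase = v$ligase)
  })
}

#' Pathway completeness per genome
#'
#' Fraction of a pathway's core genes present in each genome of a
#' gene-presence table. Genes absent from the table are treated as
#' absent. Missing genes are listed in pathway order.
#'
#' @param presence gene-presence data frame: `genome_id` column plus one
#'   0/1 (or logical) column per gene symbol.
#' @param pathway a [pathway_def()].
#' @return tibble: `genome_id`, `cofactor`, `n_core`, `n_present`,
#'   `score`, `missing` (list-column of symbols).
#' @export
completeness <- function(presence, pathway) {
  stopifnot(inherits(pathway, "pathway_def"))
  pres <- check_presence(presence)
  core <- pathway$core_genes
  have <- vapply(core, function(g) {
    if (g %in% names(pres)) as.logical(pres[[g]]) else rep(FALSE, nrow(pres))
  }, logical(nrow(pres)))
  have <- matrix(have, nrow = nrow(pres),
                 dimnames = list(NULL, core))
  tibble(genome_id = pres$genome_id,
         cofactor = pathway$cofactor,
         n_core = length(core),
         n_present = as.integer(rowSums(have)),
         score = rowSums(have) / length(core),
         missing = purrr::map(seq_len(nrow(pres)),
                              function(i) core[!have[i, ]]))
}

check_presence <- function(presence) {
  if (!is.data.frame(presence) || !"genome_id" %in% names(presence)) {
    abort("`presence` must be a data frame with a genome_id column")
  }
  as_tibble(presence)
}

#' Classify genomes as prototrophs or auxotrophs for a cofactor
#'
#' A genome is a `prototroph` when its pathway completeness reaches
#' `prototroph_min` (default 1: the full core set, matching a strict
#' de novo synthesis requirement); otherwise it is an
#' `auxotroph_salvage` if any salvage transporter gene is present, else
#' an `auxotroph`.
#'
#' @inheritParams completeness
#' @param prototroph_min completeness required for prototrophy
#'   (default 1.0).
#' @return the [completeness()] tibble plus `salvage` (logical) and
#'   `trophy` columns.
#' @export
classify_trophy <- function(presence, pathway, prototroph_min = 1.0) {
  comp <- completeness(presence, pathway)
  pres <- check_presence(presence)
  sal <- pathway$salvage_genes
  has_salvage <- if (length(sal) == 0) rep(FALSE, nrow(pres)) else {
    sm <- matrix(vapply(sal, function(g) {
      if (g %in% names(pres)) as.logical(pres[[g]]) else rep(FALSE, nrow(pres))
    }, logical(nrow(pres))), nrow = nrow(pres))
    rowSums(sm) > 0
  }
  comp |>
    mutate(salvage = has_salvage,
           trophy = dplyr::case_when(
             .data$score >= prototroph_min ~ "prototroph",
             .data$salvage ~ "auxotroph_salvage",
             TRUE ~ "auxotroph"))
}

#' Nominate syntrophic donor-recipient group pairs
#'
#' Joins genome trophy classes (aggregated to taxonomic groups) with the
#' positively associated group pairs of a co-occurrence network: a
#' candidate is emitted for every positive net-sign association in which
#' one group can synthesize the cofactor de novo (prototroph) and the
#' other cannot (auxotroph, with or without a salvage route). Negative
#' or mixed associations never yield candidates.
#'
#' @param trophy a [classify_trophy()] tibble with an additional `group`
#'   column (or supply `lineage`), one or more genomes per group. A group
#'   counts as prototroph (resp. auxotroph) when the majority of its
#'   genomes are; groups with a tied or unmappable class are skipped.
#' @param associations a [group_associations()] tibble.
#' @param lineage optional tibble `(genome_id, group)` mapping genomes to
#'   association groups when `trophy` lacks a `group` column.
#' @return tibble: `donor`, `recipient`, `cofactor`, `n_pos`, `n_neg`.
#' @export
syntrophy_candidates <- function(trophy, associations, lineage = NULL) {
  tr <- as_tibble(trophy)
  if (!"group" %in% names(tr)) {
    if (is.null(lineage)) abort("`trophy` needs a group column (or supply `lineage`)")
    tr <- tr |> left_join(as_tibble(lineage), by = "genome_id")
  }
  unmapped <- tr |> filter(is.na(.data$group))
  if (nrow(unmapped)) {
    warn(paste0("skipping genomes with no group mapping: ",
                paste(head(unmapped$genome_id, 5), collapse = ", ")))
    tr <- tr |> filter(!is.na(.data$group))
  }
  grp_class <- tr |>
    group_by(.data$group, .data$cofactor) |>
    summarise(n_proto = sum(.data$trophy == "prototroph"),
              n_auxo = sum(.data$trophy != "prototroph"),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_proto > .data$n_auxo ~ "prototroph",
      .data$n_auxo > .data$n_proto ~ "auxotroph",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$class))
  pos <- as_tibble(associations) |>
    filter(.data$net_sign == "positive", .data$group_a != .data$group_b)
  out <- purrr::map_dfr(unique(grp_class$cofactor), function(cf) {
    cls <- grp_class |> filter(.data$cofactor == cf)
    lab <- setNames(cls$class, cls$group)
    both <- bind_rows(
      pos |> mutate(donor = .data$group_a, recipient = .data$group_b),
      pos |> mutate(donor = .data$group_b, recipient = .data$group_a))
    both |>
      filter(!is.na(lab[.data$donor]), !is.na(lab[.data$recipient]),
             lab[.data$donor] == "prototroph",
             lab[.data$recipient] == "auxotroph") |>
      mutate(cofactor = cf) |>
      select("donor", "recipient", "cofactor", "n_pos", "n_neg")
  })
  out |> distinct() |> arrange(.data$cofactor, .data$donor, .data$recipient)
}
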