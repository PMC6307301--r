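#' Read a counts TSV
#'
#' Rows are features, the first column their ids, remaining columns
#' per-sample integer counts.
#'
#' @param path TSV file.
#' @return wide count tibble (first column renamed `feature_id`).
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  check_counts(x)
  x
}

#' Read sample metadata TSV
#'
#' Columns `sample_id`, `source`, `day` and optionally `molecule`.
#'
#' @param path TSV file.
#' @return tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  check_meta(md)
  md
}

#' Read a taxonomy TSV
#'
#' Either one rank per column, or two columns (`feature_id`, `lineage`)
#' with seven semicolon-joined ranks which are split into
#' domain/phylum/class/order/family/genus/species.
#'
#' @param path TSV file.
#' @return tibble with `feature_id` and rank columns.
#' @export
read_taxonomy <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  if (ncol(x) == 2) {
    x <- tidyr::separate(x, 2,
                         into = c("domain", "phylum", "class", "order",
                                  "family", "genus", "species"),
                         sep = ";", fill = "right")
  }
  x
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  as_seq_vector(Biostrings::readDNAStringSet(path), "fasta")
}
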