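#' Percent identity between two nucleotide sequences
#'
#' Semi-global (end-gap-free) alignment under match +1, mismatch -1, gap
#' open -2, gap extend -1 (a gap run of length L costs 2 + (L - 1)).
#' Identity is matches over aligned columns, terminal overhangs excluded;
#' internal gap columns count in the denominator; columns involving N
#' never count as matches. Among score-tied alignments the one with the
#' most matches, then the fewest columns, defines identity and overlap —
#' a symmetric rule, so swapping the sequences never changes the result.
#'
#' @param seq_a,seq_b nucleotide strings over `{A,C,G,T,N}` (case
#'   insensitive); must be non-empty.
#' @return one-row tibble: `identity` (proportion), `overlap` (aligned
#'   columns excluding terminal gaps), `matches`, `score`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- toupper(as.character(seq_a)[1])
  b <- toupper(as.character(seq_b)[1])
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty")
  }
  check_alphabet(setNames(c(a, b), c("seq_a", "seq_b")))
  res <- .align_pair_cpp(a, b)
  tibble(identity = res$identity, overlap = res$overlap,
         matches = res$matches, score = res$score)
}

kmer_set <- function(s, k = 12) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1), k:n))
}

# number of distinct k-mers shared by two sequences
shared_kmer_count <- function(a, b, k = 12) {
  length(intersect(kmer_set(a, k), kmer_set(b, k)))
}

# is the shared-k-mer prefilter sound for this identity/overlap gate?
# at identity >= mi over overlap >= mo columns, non-matches d satisfy
# d <= (1 - mi) * w, so the longest exact run is >= mi * w / (d + 1),
# minimized at w = mo; skip alignment only when even that run is >= k
prefilter_sound <- function(min_identity, min_overlap, k = 12) {
  w <- min_overlap
  run <- floor(min_identity * w / ((1 - min_identity) * w + 1))
  run >= k
}

#' Recruit amplicon features to a cultured isolate by identity
#'
#' Maps an isolate's near-full-length 16S sequence to representative
#' amplicon features: a feature is recruited when the pairwise identity is
#' at least `min_identity` over at least `min_overlap` aligned columns.
#' Recruited reads per sample are the column sums of all matched features
#' (features at or above the identity gate are treated as the same
#' species, so their reads add). Zero matches yield an all-zero profile,
#' not an error.
#'
#' A shared 12-mer prefilter skips alignments that provably cannot reach
#' the gate (a >= 99% match over >= 200 columns must contain a >= 12-nt
#' exact run); it is disabled automatically when the gate is loose enough
#' that the guarantee fails, so results never depend on it.
#'
#' @param isolates isolate sequences: named character vector, data frame
#'   (id, sequence) or `Biostrings::DNAStringSet`.
#' @param features representative feature sequences, same forms; names
#'   must be a subset of `counts` feature ids.
#' @param counts wide count tibble (feature_id + sample columns).
#' @param min_identity identity gate (default 0.99).
#' @param min_overlap minimum aligned columns (default 200 nt), the
#'   reproducible stand-in for an E-value gate on near-full-length 16S.
#' @param prefilter use the shared-k-mer screen when sound (default TRUE).
#' @return object of class `recruitment`: list with `counts` (long tibble
#'   isolate_id, sample_id, reads), `matches` (isolate_id, feature_id,
#'   identity, overlap) and `params`.
#' @export
recruit <- function(isolates, features, counts,
                    min_identity = 0.99, min_overlap = 200,
                    prefilter = TRUE) {
  iso <- as_seq_vector(isolates, "isolates")
  fea <- as_seq_vector(features, "features")
  check_alphabet(iso, "isolates"); check_alphabet(fea, "features")
  check_counts(counts)
  missing_ids <- setdiff(names(fea), counts$feature_id)
  if (length(missing_ids)) {
    abort(paste0("feature ids absent from counts: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  use_screen <- isTRUE(prefilter) && prefilter_sound(min_identity, min_overlap)
  samples <- names(counts)[-1]
  cm <- as_count_matrix(counts)

  match_rows <- list()
  profiles <- matrix(0L, nrow = length(iso), ncol = length(samples),
                     dimnames = list(names(iso), samples))
  if (use_screen) {
    iso_kmers <- lapply(iso, kmer_set)
    fea_kmers <- lapply(fea, kmer_set)
  }
  for (i in seq_along(iso)) {
    for (f in seq_along(fea)) {
      if (use_screen && !any(iso_kmers[[i]] %in% fea_kmers[[f]])) next
      al <- .align_pair_cpp(iso[i], fea[f])
      if (al$identity >= min_identity && al$overlap >= min_overlap) {
        match_rows[[length(match_rows) + 1]] <-
          tibble(isolate_id = names(iso)[i], feature_id = names(fea)[f],
                 identity = al$identity, overlap = al$overlap)
        profiles[i, ] <- profiles[i, ] + cm[names(fea)[f], ]
      }
    }
  }
  matches <- if (length(match_rows)) bind_rows(match_rows) else
    tibble(isolate_id = character(), feature_id = character(),
           identity = double(), overlap = integer())
  long <- count_tbl(profiles) |>
    rename(isolate_id = "feature_id") |>
    tidyr::pivot_longer(-"isolate_id", names_to = "sample_id", values_to = "reads")
  structure(list(counts = long, matches = matches,
                 params = list(min_identity = min_identity,
                               min_overlap = min_overlap,
                               prefilter_used = use_screen)),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat("<recruitment> ", dplyr::n_distinct(x$counts$isolate_id), " isolates, ",
      nrow(x$matches), " matched features (identity >= ",
      x$params$min_identity, ", overlap >= ", x$params$min_overlap, ")\n", sep = "")
  invisible(x)
}

#' @describeIn recruit long tibble of recruited reads per isolate and
#'   sample.
#' @param x a `recruitment` object.
#' @param ... unused.
#' @export
tidy.recruitment <- function(x, ...) x$counts

#' @describeIn recruit one-row summary (isolates, matches, parameters).
#' @export
glance.recruitment <- function(x, ...) {
  tibble(n_isolates = dplyr::n_distinct(x$counts$isolate_id),
         n_matched_features = nrow(x$matches),
         min_identity = x$params$min_identity,
         min_overlap = x$params$min_overlap)
}
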