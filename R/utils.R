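# shared helpers for count tables (wide tibbles: feature_id + one column per
# sample) and their matrix form used by vegan / cor()

#' Convert a wide count tibble to an integer matrix
#'
#' @param counts data frame whose first column (`feature_id`) holds feature
#'   identifiers and whose remaining columns are per-sample integer counts.
#' @return numeric matrix, features in rows (rownames), samples in columns.
#' @keywords internal
#' @noRd
as_count_matrix <- function(counts) {
  check_counts(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1]])
  m
}

count_tbl <- function(mat) {
  tibble::as_tibble(mat, rownames = "feature_id")
}

check_counts <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("`counts` must be a data frame: feature_id column + sample columns")
  }
  vals <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("count columns must be numeric")
  if (any(vals < 0, na.rm = TRUE)) abort("counts must be non-negative")
  if (anyDuplicated(counts[[1]])) abort("feature ids must be unique")
  invisible(counts)
}

check_meta <- function(meta, sample_ids = NULL) {
  need <- c("sample_id", "source", "day")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("`meta` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, meta$sample_id)
    if (length(absent)) {
      abort(paste0("samples absent from `meta`: ",
                   paste(head(absent, 5), collapse = ", ")))
    }
  }
  invisible(meta)
}

# sequences: accept a named character vector, a data frame
# (id, sequence), or a Biostrings::DNAStringSet; return named upper-case
# character vector
as_seq_vector <- function(x, arg = "sequences") {
  if (methods::is(x, "DNAStringSet")) {
    out <- setNames(as.character(x), names(x))
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort(paste0("`", arg, "` data frame needs id + sequence columns"))
    out <- setNames(as.character(x[[2]]), as.character(x[[1]]))
  } else if (is.character(x)) {
    out <- x
  } else {
    abort(paste0("`", arg, "` must be a named character vector, data frame or DNAStringSet"))
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    abort(paste0("`", arg, "` must carry sequence names"))
  }
  toupper(out)
}

check_alphabet <- function(seqs, arg = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("`", arg, "` contains characters outside {A,C,G,T,N}: ",
                 paste(head(names(seqs)[bad], 3), collapse = ", ")))
  }
  invisible(seqs)
}

# deterministic 31-bit string hash for per-stage seed fan-out
hash_string <- function(x) {
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

# derive a child seed from a parent seed and a stage label; stable under
# insertion of other stages
child_seed <- function(seed, label) {
  as.integer((as.double(seed) * 48271 + hash_string(label)) %% 2147483647)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# vegan::rrarefy warns whenever the smallest positive count exceeds 1
# (a heads-up about relative-abundance input); counts here are validated
# integers and depths are pre-checked, so that advisory is muffled
quiet_rrarefy <- function(x, sample) {
  withCallingHandlers(
    vegan::rrarefy(x, sample),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
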