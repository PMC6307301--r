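# Independent oracles used across the suite. Each reimplements the checked
# operation from its definition, sharing no code with the package internals.

# Brute-force semi-global alignment oracle: full-matrix Gotoh DP over
# (score, matches, columns) tuples with the same objective the package
# documents (max score, then max matches, then min columns; match +1,
# mismatch -1, gap run open 2 / extend 1; free terminal overhangs; N never
# matches). Written for clarity, not speed: intended for short sequences.
oracle_align <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  la <- length(a); lb <- length(b)
  worse <- c(-Inf, -Inf, Inf)
  lex_max <- function(u, v) {
    if (u[1] != v[1]) return(if (u[1] > v[1]) u else v)
    if (u[2] != v[2]) return(if (u[2] > v[2]) u else v)
    if (u[3] <= v[3]) u else v
  }
  M <- X <- Y <- array(rep(worse, (la + 1) * (lb + 1)),
                       dim = c(3, la + 1, lb + 1))
  for (i in 0:la) M[, i + 1, 1] <- c(0, 0, 0)
  for (j in 0:lb) M[, 1, j + 1] <- c(0, 0, 0)
  best <- worse
  for (i in 1:la) {
    for (j in 1:lb) {
      mt <- a[i] == b[j] && a[i] %in% c("A", "C", "G", "T")
      pred <- lex_max(lex_max(M[, i, j], X[, i, j]), Y[, i, j])
      if (is.finite(pred[1])) {
        M[, i + 1, j + 1] <- pred + c(if (mt) 1 else -1, if (mt) 1 else 0, 1)
      }
      X[, i + 1, j + 1] <- lex_max(M[, i, j + 1] + c(-2, 0, 1),
                                   X[, i, j + 1] + c(-1, 0, 1))
      Y[, i + 1, j + 1] <- lex_max(M[, i + 1, j] + c(-2, 0, 1),
                                   Y[, i + 1, j] + c(-1, 0, 1))
      if (i == la || j == lb) best <- lex_max(best, M[, i + 1, j + 1])
    }
  }
  list(score = best[1], identity = best[2] / best[3], overlap = best[3])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# mutate exactly k sites of a sequence (substitutions only)
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  for (s in sample(length(ch), k)) ch[s] <- sample(setdiff(c("A", "C", "G", "T"), ch[s]), 1)
  paste(ch, collapse = "")
}

# Exhaustive all-pairs network oracle: hand-rolled Pearson correlation on
# log10 counts with zeros as missing, pairwise-complete samples
oracle_edges <- function(counts, threshold = 0.7, min_pairs = 9) {
  m <- as.matrix(counts[, -1]); rownames(m) <- counts[[1]]
  lm <- log10(m); lm[m == 0] <- NA
  ids <- rownames(m)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      xi <- lm[i, ]; xj <- lm[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) < min_pairs) next
      x <- xi[ok]; y <- xj[ok]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      if (is.finite(r) && abs(r) >= threshold) {
        pair <- sort(c(ids[i], ids[j]))
        out[[length(out) + 1]] <- data.frame(
          feature_a = pair[1], feature_b = pair[2], r = r)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(feature_a = character(), feature_b = character(), r = double())
}

# small deterministic count table builder
toy_counts <- function(mat, ids = sprintf("f%02d", seq_len(nrow(mat)))) {
  colnames(mat) <- colnames(mat) %||% sprintf("s%02d", seq_len(ncol(mat)))
  tibble::as_tibble(cbind(data.frame(feature_id = ids), mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny paired-library fixture for activity tests: builds wide RNA/DNA
# tables plus metadata from long (feature, source, day, rna, dna) input
toy_paired <- function(df) {
  wide <- function(df, col, mol) {
    w <- tidyr::pivot_wider(
      dplyr::mutate(df, sample_id = sprintf("%s_d%02d_%s", source, day, mol)),
      id_cols = "feature_id", names_from = "sample_id",
      values_from = dplyr::all_of(col), values_fill = 0)
    w
  }
  rna <- wide(df, "rna", "RNA"); dna <- wide(df, "dna", "DNA")
  keys <- unique(df[, c("source", "day")])
  meta <- rbind(
    data.frame(sample_id = sprintf("%s_d%02d_RNA", keys$source, keys$day),
               source = keys$source, day = keys$day, molecule = "RNA"),
    data.frame(sample_id = sprintf("%s_d%02d_DNA", keys$source, keys$day),
               source = keys$source, day = keys$day, molecule = "DNA"))
  list(rna = rna, dna = dna, meta = meta)
}
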