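#' Rarefy a count table to a common depth
#'
#' Subsamples every sample (column) without replacement to exactly
#' `depth` reads, the normalization used before all downstream ratios and
#' diversity comparisons. A single recorded draw is used (reporting
#' functions that need averaging, like [rarefaction_curve()], repeat the
#' draw themselves).
#'
#' @param counts wide count tibble (feature_id + sample columns).
#' @param depth target reads per sample, or `"min"` for the smallest
#'   column sum.
#' @param seed integer seed making the draw reproducible.
#' @return wide count tibble; every column sums to `depth`.
#' @export
rarefy <- function(counts, depth = "min", seed = NULL) {
  m <- as_count_matrix(counts)
  totals <- colSums(m)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) abort("depth must be positive")
  short <- totals < depth
  if (any(short)) {
    abort(paste0("depth ", depth, " exceeds the total of sample(s): ",
                 paste(head(names(totals)[short], 5), collapse = ", ")))
  }
  out <- with_seed_if(seed, t(quiet_rrarefy(t(m), depth)))
  storage.mode(out) <- "integer"
  count_tbl(out)
}

#' Alpha-diversity estimators per sample
#'
#' Observed richness, singleton/doubleton counts, bias-corrected Chao1,
#' ACE (with its components), Shannon entropy (natural log) and Simpson
#' indices for every sample of a count table. Simpson is reported both as
#' the Gini-Simpson form `1 - sum(p^2)` (`simpson`) and as the raw
#' concentration `sum(p^2)` (`dominance`), since conventions differ.
#'
#' @param counts wide count tibble.
#' @param rare_cutoff abundance cutoff separating rare from abundant
#'   species in ACE (default 10).
#' @return tibble, one row per sample: `sample_id`, `s_obs`, `f1`, `f2`,
#'   `chao1`, `ace`, `s_rare`, `s_abund`, `c_ace`, `gamma_ace`,
#'   `shannon`, `simpson`, `dominance`.
#' @export
alpha_diversity <- function(counts, rare_cutoff = 10) {
  m <- as_count_matrix(counts)
  purrr::map_dfr(colnames(m), function(s) {
    x <- m[, s]
    a <- ace(x, rare_cutoff = rare_cutoff, detail = TRUE)
    tibble(sample_id = s,
           s_obs = sum(x > 0), f1 = sum(x == 1), f2 = sum(x == 2),
           chao1 = chao1(x), ace = a$ace,
           s_rare = a$s_rare, s_abund = a$s_abund,
           c_ace = a$c_ace, gamma_ace = a$gamma,
           shannon = shannon(x), simpson = simpson(x),
           dominance = 1 - simpson(x))
  })
}

#' Shannon entropy of a count vector
#'
#' `H = -sum(p_i * ln(p_i))` over positive counts.
#'
#' @param x non-negative count vector with at least one positive entry.
#' @return Shannon index (nats).
#' @export
shannon <- function(x) {
  check_column(x)
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Gini-Simpson index of a count vector
#'
#' `D = 1 - sum(p_i^2)`; lies in `[0, 1)`.
#'
#' @inheritParams shannon
#' @return Gini-Simpson index.
#' @export
simpson <- function(x) {
  check_column(x)
  as.numeric(vegan::diversity(x, index = "simpson"))
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, which never divides by zero
#' and reduces to `S_obs` when there are no singletons.
#'
#' @inheritParams shannon
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(x) {
  check_column(x)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimator (Chao & Lee)
#'
#' Abundance-based coverage estimator with rare/abundant cutoff
#' `rare_cutoff`: rare species (counts <= cutoff) contribute through the
#' sample coverage `C_ace = 1 - F1 / N_rare` and the rare-class
#' coefficient of variation `gamma^2`. When every rare species is a
#' singleton the coverage is zero and the estimator falls back to Chao1
#' (the standard convention).
#'
#' @inheritParams shannon
#' @param rare_cutoff abundance cutoff (default 10).
#' @param detail return the components as a one-row tibble instead of the
#'   single estimate.
#' @return ACE estimate, or a tibble with `ace`, `s_rare`, `s_abund`,
#'   `n_rare`, `c_ace`, `gamma`.
#' @export
ace <- function(x, rare_cutoff = 10, detail = FALSE) {
  check_column(x)
  rare <- x[x > 0 & x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (s_rare == 0) {
    out <- list(ace = s_abund, s_rare = 0, s_abund = s_abund,
                n_rare = 0, c_ace = NA_real_, gamma = NA_real_)
  } else if (n_rare == f1) {
    out <- list(ace = chao1(x), s_rare = s_rare, s_abund = s_abund,
                n_rare = n_rare, c_ace = 0, gamma = NA_real_)
  } else {
    c_ace <- 1 - f1 / n_rare
    fi <- tabulate(rare, nbins = rare_cutoff)
    i <- seq_len(rare_cutoff)
    g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
    out <- list(ace = s_abund + s_rare / c_ace + f1 / c_ace * g2,
                s_rare = s_rare, s_abund = s_abund, n_rare = n_rare,
                c_ace = c_ace, gamma = g2)
  }
  if (detail) as_tibble(out) else out$ace
}

check_column <- function(x) {
  if (!is.numeric(x) || length(x) == 0) abort("need a numeric count vector")
  if (any(x < 0)) abort("counts must be non-negative")
  if (sum(x) == 0) abort("all-zero column: diversity is undefined")
  invisible(x)
}

#' Monte-Carlo rarefaction curves
#'
#' Mean observed richness (and mean Shannon index) at a ladder of
#' subsampling depths, averaged over `reps` random draws per depth. At a
#' depth equal to the sample's full total the curve equals the raw
#' observed values exactly.
#'
#' @param counts wide count tibble.
#' @param depths ascending depths; default: 10 points from 1 to each
#'   sample's total (per sample).
#' @param reps random subsamples averaged per depth (>= 1, default 10).
#' @param seed integer seed.
#' @return tibble: `sample_id`, `depth`, `mean_s_obs`, `mean_shannon`.
#' @export
rarefaction_curve <- function(counts, depths = NULL, reps = 10, seed = NULL) {
  if (reps < 1) abort("reps must be >= 1")
  m <- as_count_matrix(counts)
  with_seed_if(seed, {
    purrr::map_dfr(colnames(m), function(s) {
      x <- m[, s]
      total <- sum(x)
      dd <- if (is.null(depths)) unique(round(seq(1, total, length.out = 10))) else depths
      if (any(dd > total)) {
        abort(paste0("depth exceeds the total of sample ", s))
      }
      if (is.unsorted(dd)) abort("depths must be ascending")
      purrr::map_dfr(dd, function(d) {
        draws <- purrr::map(seq_len(reps), function(r) {
          if (d == total) x else drop(quiet_rrarefy(t(as.matrix(x)), d))
        })
        tibble(sample_id = s, depth = d,
               mean_s_obs = mean(purrr::map_dbl(draws, ~ sum(.x > 0))),
               mean_shannon = mean(purrr::map_dbl(draws, shannon)))
      })
    })
  })
}

#' Novel-OTU gain after enrichment
#'
#' Features detected after enrichment but absent from the day-0 libraries,
#' relative to day-0 richness — the "new taxa surfaced by culturing"
#' statistic. Because the phrase "x% more OTUs" can also mean the net
#' richness change, both are returned: `gain` = novel / day-0 richness,
#' and `richness_change` = (post-enrichment richness - day-0 richness) /
#' day-0 richness. Computed per source and pooled; samples should be
#' rarefied to a common depth first.
#'
#' @param counts wide count tibble (typically DNA libraries, rarefied).
#' @param meta sample metadata with `sample_id`, `source`, `day` (and
#'   optionally `molecule`, in which case only DNA samples are used).
#' @return tibble: `source` (sources plus `"pooled"`), `n_day0`,
#'   `n_novel`, `n_post`, `gain`, `richness_change`.
#' @export
novel_otu_gain <- function(counts, meta) {
  check_counts(counts)
  check_meta(meta, names(counts)[-1])
  md <- meta |> filter(.data$sample_id %in% names(counts)[-1])
  if ("molecule" %in% names(md) && any(md$molecule == "DNA")) {
    md <- md |> filter(.data$molecule == "DNA")
  }
  m <- as_count_matrix(counts)[, md$sample_id, drop = FALSE]
  one <- function(samples0, samples1, label) {
    f0 <- rownames(m)[rowSums(m[, samples0, drop = FALSE]) > 0]
    f1 <- rownames(m)[rowSums(m[, samples1, drop = FALSE]) > 0]
    if (length(f0) == 0) abort("no features detected at day 0: gain undefined")
    tibble(source = label,
           n_day0 = length(f0),
           n_novel = length(setdiff(f1, f0)),
           n_post = length(f1),
           gain = length(setdiff(f1, f0)) / length(f0),
           richness_change = (length(f1) - length(f0)) / length(f0))
  }
  s0 <- md$sample_id[md$day == 0]
  s1 <- md$sample_id[md$day > 0]
  if (length(s0) == 0 || length(s1) == 0) {
    abort("need both day-0 and post-enrichment samples")
  }
  per_source <- purrr::map_dfr(sort(unique(md$source)), function(src) {
    a <- md$sample_id[md$day == 0 & md$source == src]
    b <- md$sample_id[md$day > 0 & md$source == src]
    if (length(a) == 0 || length(b) == 0) return(tibble())
    one(a, b, src)
  })
  bind_rows(per_source, one(s0, s1, "pooled"))
}
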