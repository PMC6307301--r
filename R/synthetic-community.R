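#' Simulation parameters for a synthetic enrichment-culture community
#'
#' Bundles the knobs of the synthetic-community generator. The defaults
#' describe a marine-sediment enrichment experiment: three sediment sources
#' followed over five time points (days 0, 5, 12, 21, 30), a community of
#' fast-blooming opportunists (r-strategists) seeded from a rare dormant
#' seed bank, slow steadily growing k-strategists, and an inert background,
#' with paired DNA (16S rRNA gene) and RNA (16S rRNA) libraries whose
#' RNA:DNA ratios encode a planted active/dormant state per taxon and day.
#'
#' @param n_sources number of sediment sources (independent replicate
#'   communities). Default 3.
#' @param days integer vector of enrichment days sampled. Default
#'   `c(0, 5, 12, 21, 30)`.
#' @param n_taxa community richness. Default 200.
#' @param depth reads per library. Default 50443, the rarefaction floor
#'   used throughout; tests and examples typically use smaller depths.
#' @param frac_r,frac_k,frac_inert proportions of r-strategist,
#'   k-strategist and inert taxa; must sum to 1.
#' @param seedbank_log10_range interval of log10 baseline relative
#'   abundance for seed-bank (r-strategist) taxa. Default `c(-5, -3)`.
#' @param bloom_log10 log10 fold-rise of an r-strategist bloom at its peak
#'   day. Default 3.5.
#' @param fall_days days over which a collapsed bloom decays back down.
#'   Default 15.
#' @param k_slope log10 increase per day for k-strategists. Default 0.08.
#' @param noise_sdlog10 per-(taxon, source, day) lognormal noise on the
#'   latent abundances, in log10 units. Default 0.15.
#' @param activity_factor_active,activity_factor_dormant multiplicative
#'   RNA scaling for active (> 1) and dormant (< 1) taxa. Defaults 4 and
#'   0.2.
#' @param active_frac_day0,active_frac_final fraction of taxa active at
#'   day 0 and at the final day; the active set shrinks linearly in
#'   between (actively growing communities paradoxically lose active
#'   taxa during enrichment). Defaults 0.27 and 0.13.
#' @param planted_edges data frame of planted inter-taxon correlations:
#'   columns `taxon_a`, `taxon_b` (1-based taxon indices) and `sign`
#'   (+1 or -1). `NULL` plants the default three pairs (two positive, one
#'   negative) among dynamic taxa placed in dedicated families.
#' @param planted_baseline_log10,planted_amp_log10 baseline and amplitude
#'   (log10) of the planted-pair trajectories; chosen so planted taxa stay
#'   detectable in every library yet swing widely enough for correlation.
#' @param seq_length reference 16S sequence length (nt). Default 1400.
#' @param isolate_divergence substitutions per site between an isolate and
#'   its source reference. Default 0.005.
#' @param n_isolates number of cultured isolates to simulate. Default 20.
#' @param rng_seed integer seed used when the generator is run without an
#'   explicit one.
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_sources = 3,
                       days = c(0, 5, 12, 21, 30),
                       n_taxa = 200,
                       depth = 50443,
                       frac_r = 0.2,
                       frac_k = 0.2,
                       frac_inert = 0.6,
                       seedbank_log10_range = c(-5, -3),
                       bloom_log10 = 3.5,
                       fall_days = 15,
                       k_slope = 0.08,
                       noise_sdlog10 = 0.15,
                       activity_factor_active = 4,
                       activity_factor_dormant = 0.2,
                       active_frac_day0 = 0.27,
                       active_frac_final = 0.13,
                       planted_edges = NULL,
                       planted_baseline_log10 = c(-2.8, -2.0),
                       planted_amp_log10 = 1.6,
                       seq_length = 1400,
                       isolate_divergence = 0.005,
                       n_isolates = 20,
                       rng_seed = 1L) {
  p <- as.list(environment())
  fr <- frac_r + frac_k + frac_inert
  if (abs(fr - 1) > 1e-8) abort("frac_r + frac_k + frac_inert must sum to 1")
  if (depth <= 0) abort("depth must be positive")
  if (n_taxa < 2) abort("n_taxa must be at least 2")
  if (!(activity_factor_dormant < 1 && activity_factor_active > 1)) {
    abort("need activity_factor_dormant < 1 < activity_factor_active")
  }
  if (!(0 %in% days)) abort("`days` must include day 0")
  if (is.null(planted_edges)) p$planted_edges <- default_planted_edges(p)
  else {
    pe <- as_tibble(planted_edges)
    if (!all(c("taxon_a", "taxon_b", "sign") %in% names(pe))) {
      abort("planted_edges needs columns taxon_a, taxon_b, sign")
    }
    if (any(pe$taxon_a == pe$taxon_b)) abort("planted edges must join distinct taxa")
    if (nrow(pe) && max(pe$taxon_a, pe$taxon_b) > n_taxa) {
      abort("planted edge index exceeds n_taxa")
    }
    p$planted_edges <- pe
  }
  structure(p, class = "sim_params")
}

# default planting: three pairs among the last six taxa (kept clear of the
# strategist blocks at the front), two positive and one negative
default_planted_edges <- function(p) {
  n <- p$n_taxa
  if (n < 12) return(tibble(taxon_a = integer(), taxon_b = integer(), sign = integer()))
  idx <- (n - 5):n
  tibble(taxon_a = idx[c(1, 3, 5)], taxon_b = idx[c(2, 4, 6)], sign = c(1L, 1L, -1L))
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$n_taxa, " taxa, ", x$n_sources, " sources, days ",
      paste(x$days, collapse = "/"), ", depth ", x$depth, "\n", sep = "")
  cat("  strategists r/k/inert: ", x$frac_r, "/", x$frac_k, "/", x$frac_inert,
      "; activity factors ", x$activity_factor_active, " (active) / ",
      x$activity_factor_dormant, " (dormant)\n", sep = "")
  invisible(x)
}

taxon_ids <- function(n) sprintf("otu%03d", seq_len(n))

# strategist class per taxon index: r block, then k block, then inert;
# planted-edge taxa are forced to class "planted" afterwards
strategist_classes <- function(p) {
  n_r <- round(p$frac_r * p$n_taxa)
  n_k <- round(p$frac_k * p$n_taxa)
  cls <- rep("inert", p$n_taxa)
  if (n_r > 0) cls[seq_len(n_r)] <- "r"
  if (n_k > 0) cls[n_r + seq_len(n_k)] <- "k"
  planted <- unique(c(p$planted_edges$taxon_a, p$planted_edges$taxon_b))
  cls[planted] <- "planted"
  cls
}

#' Simulate latent relative-abundance trajectories
#'
#' Deterministic log-linear growth/decay per strategist class plus
#' lognormal per-(taxon, source, day) noise, normalized per (source, day).
#' r-strategists rise from a rare seed-bank baseline to a bloom at an
#' interior peak day and then collapse; k-strategists grow monotonically;
#' inert taxa keep a constant expected abundance (their *relative*
#' abundance still shrinks when others bloom). Planted-pair partners get
#' trajectories that are exact log-linear functions of each other (slope
#' +1 or -1) so downstream correlation has a known sign.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; defaults to `params$rng_seed`.
#' @return tibble with columns `feature_id`, `class`, `source`, `day`,
#'   `expected` (noise-free normalized relative abundance) and
#'   `rel_abund` (realized, noisy, normalized); the realized values are
#'   what counts are later drawn from.
#' @export
simulate_trajectories <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- seed %||% params$rng_seed
  with_seed_if(seed, {
    p <- params
    n <- p$n_taxa
    ids <- taxon_ids(n)
    cls <- strategist_classes(p)
    days <- sort(unique(p$days))
    sources <- sprintf("S%d", seq_len(p$n_sources))

    # per-taxon baselines (log10, shared across sources)
    base <- numeric(n)
    base[cls == "r"] <- runif(sum(cls == "r"),
                              p$seedbank_log10_range[1], p$seedbank_log10_range[2])
    base[cls == "k"] <- runif(sum(cls == "k"), -4, -2)
    base[cls == "inert"] <- runif(sum(cls == "inert"), -4.5, -1.3)
    peak <- rep(NA_real_, n)
    interior <- setdiff(days, c(min(days), max(days)))
    peak[cls == "r"] <- sample(interior, sum(cls == "r"), replace = TRUE)

    pe <- p$planted_edges
    leaders <- pe$taxon_a
    peak[unique(c(pe$taxon_a, pe$taxon_b))] <- 0  # placeholder, set below
    peak[leaders] <- if (length(interior)) interior[1 + (seq_along(leaders) %% length(interior))] else max(days)

    shape <- function(i, t) {
      switch(cls[i],
        r = p$bloom_log10 * bloom_shape(t, peak[i], p$fall_days),
        k = p$k_slope * t,
        0)
    }

    grid <- tidyr::expand_grid(taxon = seq_len(n), source = sources, day = days)
    logw_det <- vapply(seq_len(nrow(grid)),
                       function(r) base[grid$taxon[r]] + shape(grid$taxon[r], grid$day[r]),
                       numeric(1))
    noise <- rnorm(nrow(grid), 0, p$noise_sdlog10)
    grid$logw <- logw_det + noise
    grid$logw_det <- logw_det

    # planted pairs are designed in *relative*-abundance space so their
    # log-scale correlation survives normalization: the community
    # log-total (which grows with the blooms) is added back, so the
    # pair's planned excursions are excursions of relative abundance,
    # and the partner mirrors the leader's realized (noisy) excursion
    # exactly with slope +1 or -1
    planted_all <- unique(c(pe$taxon_a, pe$taxon_b))
    if (length(planted_all)) {
      for (src in sources) {
        rows_src <- grid$source == src
        others <- rows_src & !(grid$taxon %in% planted_all)
        totals <- vapply(days, function(d)
          sum(10^grid$logw[others & grid$day == d]), numeric(1))
        logT <- log10(totals)[match(grid$day[rows_src], days)]
        bb <- mean(p$planted_baseline_log10)
        for (e in seq_len(nrow(pe))) {
          a <- pe$taxon_a[e]; b <- pe$taxon_b[e]; s <- pe$sign[e]
          ia <- which(rows_src & grid$taxon == a)
          ib <- which(rows_src & grid$taxon == b)
          tr_det <- p$planted_amp_log10 *
            (bloom_shape(grid$day[ia], peak[a], p$fall_days) - 0.5)
          tr <- tr_det + (grid$logw[ia] - grid$logw_det[ia])  # keep the noise
          lT <- log10(totals)[match(grid$day[ia], days)]
          grid$logw[ia] <- bb + tr + lT
          grid$logw_det[ia] <- bb + tr_det + lT
          grid$logw[ib] <- bb + s * (tr - mean(tr)) + lT
          grid$logw_det[ib] <- bb + s * (tr_det - mean(tr_det)) + lT
        }
      }
    }

    out <- grid |>
      mutate(feature_id = ids[.data$taxon], class = cls[.data$taxon],
             w = 10^.data$logw, w_det = 10^.data$logw_det) |>
      group_by(.data$source, .data$day) |>
      mutate(rel_abund = .data$w / sum(.data$w),
             expected = .data$w_det / sum(.data$w_det)) |>
      ungroup() |>
      select("feature_id", "class", "source", "day", "expected", "rel_abund") |>
      arrange(.data$source, .data$day, .data$feature_id)
    out
  })
}

# triangular bloom shape: 0 at day 0, 1 at the peak, linear decay over
# `fall` days afterwards (floored at 0)
bloom_shape <- function(t, peak, fall) {
  ifelse(t <= peak, t / peak, pmax(0, 1 - (t - peak) / fall))
}

#' Draw multinomial library counts from latent relative abundances
#'
#' Each sample's reads are drawn multinomially at `depth` from the
#' realized relative abundances. For `molecule = "RNA"` the DNA
#' proportions are first scaled by each taxon's activity factor for that
#' day and renormalized: a one-parameter stand-in for per-cell ribosome
#' content, sufficient because downstream analysis only consumes the
#' RNA:DNA ratio's position relative to 1.
#'
#' @param latent tibble from [simulate_trajectories()].
#' @param depth reads per sample (> 0).
#' @param molecule `"DNA"` or `"RNA"`.
#' @param activity optional tibble `(feature_id, day, factor)` of RNA
#'   scaling factors; required for RNA, ignored for DNA.
#' @param seed integer seed.
#' @return list: `counts` (wide tibble feature_id x samples) and `meta`
#'   (sample_id, source, day, molecule). Column sums equal `depth`
#'   exactly.
#' @export
sample_counts <- function(latent, depth, molecule = c("DNA", "RNA"),
                          activity = NULL, seed = NULL) {
  molecule <- match.arg(molecule)
  if (depth <= 0) abort("depth must be positive")
  if (molecule == "RNA" && is.null(activity)) {
    abort("RNA sampling needs an `activity` table of per-taxon factors")
  }
  with_seed_if(seed, {
    lat <- latent
    if (molecule == "RNA") {
      lat <- lat |>
        left_join(activity, by = c("feature_id", "day")) |>
        mutate(factor = dplyr::coalesce(.data$factor, 1)) |>
        group_by(.data$source, .data$day) |>
        mutate(rel_abund = .data$rel_abund * .data$factor,
               rel_abund = .data$rel_abund / sum(.data$rel_abund)) |>
        ungroup()
    }
    combos <- distinct(lat, .data$source, .data$day) |> arrange(.data$source, .data$day)
    ids <- sort(unique(lat$feature_id))
    cols <- vector("list", nrow(combos))
    for (i in seq_len(nrow(combos))) {
      sub <- lat |> filter(.data$source == combos$source[i], .data$day == combos$day[i])
      pr <- sub$rel_abund[match(ids, sub$feature_id)]
      cols[[i]] <- as.integer(rmultinom(1, size = depth, prob = pr))
    }
    m <- do.call(cbind, cols)
    colnames(m) <- sprintf("%s_d%02d_%s", combos$source, combos$day, molecule)
    rownames(m) <- ids
    meta <- tibble(sample_id = colnames(m), source = combos$source,
                   day = combos$day, molecule = molecule)
    list(counts = count_tbl(m), meta = meta)
  })
}

#' Generate reference and isolate 16S sequences
#'
#' Random A/C/G/T references, one per taxon, resampled until mutually
#' below 97% identity; each isolate is its source reference with
#' `Binomial(seq_length, divergence)` substitutions at uniformly chosen
#' sites. Mutual dissimilarity is checked with a sound 12-mer screen:
#' at >= 97% identity over ~1400 aligned columns a pair must share at
#' least 21 distinct 12-mers, so pairs sharing fewer than 10 are accepted
#' without alignment and only screen survivors are aligned.
#'
#' @param n_taxa number of reference sequences.
#' @param seq_length sequence length (nt).
#' @param isolate_divergence substitutions per site, in `[0, 0.05]`.
#' @param isolate_taxa integer indices of taxa that get an isolate
#'   (default: all).
#' @param seed integer seed.
#' @param max_retries resampling attempts per offending reference before
#'   giving up.
#' @return list: `references` and `isolates` (named character vectors;
#'   isolate names `iso_<feature_id>`), and `isolate_map` tibble
#'   (isolate_id, feature_id, n_substitutions).
#' @export
generate_sequences <- function(n_taxa, seq_length = 1400,
                               isolate_divergence = 0.005,
                               isolate_taxa = seq_len(n_taxa),
                               seed = NULL, max_retries = 20) {
  if (isolate_divergence < 0 || isolate_divergence > 0.05) {
    abort("isolate_divergence must lie in [0, 0.05]")
  }
  with_seed_if(seed, {
    ids <- taxon_ids(n_taxa)
    draw <- function() paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
                             collapse = "")
    refs <- vapply(seq_len(n_taxa), function(i) draw(), character(1))
    names(refs) <- ids
    # dissimilarity screen (cached 12-mer sets) + alignment fallback
    km <- lapply(refs, kmer_set)
    for (i in seq_len(n_taxa)) {
      tries <- 0
      repeat {
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          if (sum(km[[i]] %in% km[[j]]) >= 10 &&
              pairwise_identity(refs[i], refs[j])$identity >= 0.97) {
            ok <- FALSE
            break
          }
        }
        if (ok) break
        tries <- tries + 1
        if (tries > max_retries) abort("could not satisfy mutual dissimilarity constraint")
        refs[i] <- draw()
        km[[i]] <- kmer_set(refs[i])
      }
    }
    iso <- vapply(isolate_taxa, function(i) mutate_sequence(refs[i], isolate_divergence),
                  character(1))
    iso_ids <- paste0("iso_", ids[isolate_taxa])
    names(iso) <- iso_ids
    nsub <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                   refs[isolate_taxa], iso)
    list(references = refs, isolates = iso,
         isolate_map = tibble(isolate_id = iso_ids, feature_id = ids[isolate_taxa],
                              n_substitutions = as.integer(nsub)))
  })
}

mutate_sequence <- function(seq, divergence) {
  L <- nchar(seq)
  k <- rbinom(1, L, divergence)
  if (k == 0) return(seq)
  sites <- sample.int(L, k)
  chars <- strsplit(seq, "")[[1]]
  for (s in sites) {
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a full enrichment-culture community with planted truth
#'
#' Runs [simulate_trajectories()], draws paired DNA and RNA libraries with
#' [sample_counts()], assigns activity states (a fraction of taxa active
#' at day 0, the active set shrinking linearly towards the final day),
#' builds a synthetic 7-rank taxonomy in which planted-pair taxa occupy
#' dedicated families, and (optionally) generates reference and isolate
#' sequences with isolation metadata.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; defaults to `params$rng_seed`. Sub-stages use
#'   seeds derived deterministically from it.
#' @param sequences generate reference/isolate sequences? (sequence
#'   generation dominates run time for large `n_taxa`; stages that only
#'   need counts can skip it).
#' @return object of class `enrich_sim`: list with `counts_dna`,
#'   `counts_rna`, `meta`, `taxonomy`, `truth` (strategists, enriched,
#'   active, planted_edges, isolate_map), `latent`, `sequences`
#'   (references/isolates or NULL) and `params`.
#' @export
simulate_community <- function(params = sim_params(), seed = NULL,
                               sequences = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  seed <- as.integer(seed %||% params$rng_seed)
  p <- params
  days <- sort(unique(p$days))
  lat <- simulate_trajectories(p, seed = child_seed(seed, "trajectories"))

  activity <- assign_activity(p, seed = child_seed(seed, "activity"))
  act_factors <- activity |>
    mutate(factor = if_else(.data$true_active,
                            p$activity_factor_active, p$activity_factor_dormant)) |>
    select("feature_id", "day", "factor")

  dna <- sample_counts(lat, p$depth, "DNA", seed = child_seed(seed, "dna"))
  rna <- sample_counts(lat, p$depth, "RNA", activity = act_factors,
                       seed = child_seed(seed, "rna"))

  # realized-truth enrichment flag: did the taxon's realized relative
  # abundance in this flask exceed its own day-0 value?
  day0 <- lat |> filter(.data$day == 0) |>
    select("feature_id", "source", rel0 = "rel_abund")
  enriched <- lat |>
    left_join(day0, by = c("feature_id", "source")) |>
    mutate(true_enriched = .data$day > 0 & .data$rel_abund > .data$rel0) |>
    select("feature_id", "source", "day", "true_enriched")

  cls <- tibble(feature_id = taxon_ids(p$n_taxa), class = strategist_classes(p))
  taxonomy <- synthetic_taxonomy(p)

  seqs <- NULL
  isolate_map <- tibble(isolate_id = character(), feature_id = character(),
                        source = character(), isolation_day = integer())
  if (isTRUE(sequences)) {
    iso_taxa <- with_seed_if(child_seed(seed, "isolate-choice"),
                             sort(sample.int(p$n_taxa, min(p$n_isolates, p$n_taxa))))
    seqs <- generate_sequences(p$n_taxa, p$seq_length, p$isolate_divergence,
                               isolate_taxa = iso_taxa,
                               seed = child_seed(seed, "sequences"))
    isolate_map <- with_seed_if(child_seed(seed, "isolation-meta"), {
      seqs$isolate_map |>
        mutate(source = sample(sprintf("S%d", seq_len(p$n_sources)), n(), replace = TRUE),
               isolation_day = sample(days[days > 0], n(), replace = TRUE)) |>
        select("isolate_id", "feature_id", "source", "isolation_day")
    })
  }

  structure(list(
    counts_dna = dna$counts, counts_rna = rna$counts,
    meta = bind_rows(dna$meta, rna$meta),
    taxonomy = taxonomy,
    truth = list(strategists = cls, enriched = enriched,
                 active = activity, planted_edges = p$planted_edges,
                 isolate_map = isolate_map),
    latent = lat, sequences = seqs, params = p, seed = seed
  ), class = "enrich_sim")
}

# active/dormant schedule: day-0 active taxa drawn at active_frac_day0;
# each stays active through day t with probability f(t)/f(0) (nested
# decline), where f interpolates linearly to active_frac_final
assign_activity <- function(p, seed = NULL) {
  with_seed_if(seed, {
    days <- sort(unique(p$days))
    tmax <- max(days)
    f <- function(t) p$active_frac_day0 +
      (p$active_frac_final - p$active_frac_day0) * t / tmax
    ids <- taxon_ids(p$n_taxa)
    u <- runif(p$n_taxa)             # activity rank: active at t iff u < f(t)
    tidyr::expand_grid(feature_id = ids, day = days) |>
      mutate(true_active = u[match(.data$feature_id, ids)] < f(.data$day))
  })
}

# 7-rank synthetic lineage; ~10 families cycled over taxa, planted taxa in
# dedicated single-member families so family-level association signs are
# identifiable
synthetic_taxonomy <- function(p) {
  n <- p$n_taxa
  ids <- taxon_ids(n)
  fam <- sprintf("Family%02d", 1 + (seq_len(n) %% 10))
  ord <- sprintf("Order%02d", 1 + (seq_len(n) %% 5))
  phy <- sprintf("Phylum%02d", 1 + (seq_len(n) %% 3))
  pe <- p$planted_edges
  planted <- sort(unique(c(pe$taxon_a, pe$taxon_b)))
  fam[planted] <- sprintf("PlantedFam%02d", seq_along(planted))
  tibble(feature_id = ids,
         domain = "Bacteria", phylum = phy,
         class = sprintf("Class%02d", 1 + (seq_len(n) %% 4)),
         order = ord, family = fam,
         genus = sprintf("Genus%03d", seq_len(n)),
         species = sprintf("species%03d", seq_len(n)))
}

#' @export
print.enrich_sim <- function(x, ...) {
  cat("<enrich_sim> ", x$params$n_taxa, " taxa, ",
      ncol(x$counts_dna) - 1L, " DNA + ", ncol(x$counts_rna) - 1L,
      " RNA libraries at depth ", x$params$depth, " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_community long tidy table of counts with metadata
#'   and planted truth joined on.
#' @param x an `enrich_sim` object.
#' @param ... unused.
#' @export
tidy.enrich_sim <- function(x, ...) {
  long <- function(counts) {
    tidyr::pivot_longer(counts, -"feature_id",
                        names_to = "sample_id", values_to = "reads")
  }
  bind_rows(long(x$counts_dna), long(x$counts_rna)) |>
    left_join(x$meta, by = "sample_id") |>
    left_join(x$truth$strategists, by = "feature_id") |>
    left_join(x$truth$enriched, by = c("feature_id", "source", "day")) |>
    left_join(x$truth$active, by = c("feature_id", "day"))
}

#' @describeIn simulate_community one-row summary of the simulation.
#' @export
glance.enrich_sim <- function(x, ...) {
  tibble(n_taxa = x$params$n_taxa,
         n_samples = nrow(x$meta),
         depth = x$params$depth,
         n_isolates = nrow(x$truth$isolate_map),
         n_planted_edges = nrow(x$truth$planted_edges),
         seed = x$seed)
}

#' Write a simulated community to plain-text files
#'
#' Writes counts (DNA and RNA) TSVs, sample metadata, taxonomy, reference
#' and isolate FASTA (when present) and the planted truth as JSON.
#'
#' @param sim an `enrich_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_community <- function(sim, dir) {
  stopifnot(inherits(sim, "enrich_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts_dna = file.path(dir, "counts_dna.tsv"),
    counts_rna = file.path(dir, "counts_rna.tsv"),
    meta = file.path(dir, "sample_metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    truth = file.path(dir, "truth.json"))
  readr::write_tsv(sim$counts_dna, paths["counts_dna"])
  readr::write_tsv(sim$counts_rna, paths["counts_rna"])
  readr::write_tsv(sim$meta, paths["meta"])
  tax <- sim$taxonomy |>
    mutate(lineage = paste(.data$domain, .data$phylum, .data$class, .data$order,
                           .data$family, .data$genus, .data$species, sep = ";")) |>
    select("feature_id", "lineage")
  readr::write_tsv(tax, paths["taxonomy"])
  jsonlite::write_json(lapply(sim$truth, function(t) t), paths["truth"],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$sequences)) {
    paths <- c(paths,
               references = file.path(dir, "references.fasta"),
               isolates = file.path(dir, "isolates.fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences$references),
                                paths["references"])
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences$isolates),
                                paths["isolates"])
    readr::write_tsv(sim$truth$isolate_map, file.path(dir, "isolate_metadata.tsv"))
    paths <- c(paths, isolate_meta = file.path(dir, "isolate_metadata.tsv"))
  }
  invisible(paths)
}
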