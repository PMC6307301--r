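test_that("pseudocounted ratios are exact on boundary cases", {
  expect_equal(enrichment_ratio(0, 0), 1)
  expect_equal(enrichment_ratio(251, 0), 252)
  expect_equal(enrichment_ratio(3, 7), 0.5)
  expect_equal(activity_ratio(0, 0), 1)
  expect_equal(activity_ratio(10, 4), 2.2)
  expect_error(enrichment_ratio(-1, 0), "non-negative")
  expect_error(activity_ratio(0, -2), "non-negative")
  # boundary identity: equal counts always give exactly 1
  x <- c(0, 1, 9, 100)
  expect_equal(activity_ratio(x, x), rep(1, 4))
})

test_that("ratios are strictly monotone in each argument", {
  a <- 0:50
  expect_true(all(diff(enrichment_ratio(a, 10)) > 0))
  expect_true(all(diff(enrichment_ratio(10, a)) < 0))
})

enrich_fixture <- function(reads_by_day) {
  # one isolate in source S1, isolated at day 12
  days <- c(0, 5, 12, 21, 30)
  meta <- data.frame(sample_id = sprintf("S1_d%02d_DNA", days),
                     source = "S1", day = days, molecule = "DNA")
  rec <- data.frame(isolate_id = "isoA",
                    sample_id = meta$sample_id,
                    reads = reads_by_day)
  iso <- data.frame(isolate_id = "isoA", source = "S1", isolation_day = 12)
  list(rec = rec, meta = meta, iso = iso)
}

test_that("enrichment classification applies the > 1 boundary per isolate", {
  fx <- enrich_fixture(c(0, 10, 251, 5, 0))
  calls <- classify_enrichment(fx$rec, fx$meta, fx$iso)
  expect_equal(calls$calls$ratio, 252)
  expect_true(calls$calls$enriched)
  expect_equal(calls$summary$frac_not_enriched, 0)
  # equal abundance at the isolation day is NOT enriched (boundary)
  fx2 <- enrich_fixture(c(9, 1, 9, 1, 1))
  calls2 <- classify_enrichment(fx2$rec, fx2$meta, fx2$iso)
  expect_equal(calls2$calls$ratio, 1)
  expect_false(calls2$calls$enriched)
  expect_equal(calls2$summary$frac_not_enriched, 1)
  # missing day-0 sample is a consistency error
  fx3 <- enrich_fixture(c(1, 1, 1, 1, 1))
  expect_error(
    classify_enrichment(fx3$rec[fx3$rec$sample_id != "S1_d00_DNA", ],
                        fx3$meta[fx3$meta$day != 0, ], fx3$iso),
    "day-0")
})

test_that("day-0 isolates are excluded from the not-enriched fraction", {
  days <- c(0, 5)
  meta <- data.frame(sample_id = sprintf("S1_d%02d_DNA", days),
                     source = "S1", day = days, molecule = "DNA")
  rec <- tidyr::expand_grid(isolate_id = c("direct", "cultured"),
                            sample_id = meta$sample_id)
  rec$reads <- c(5, 5, 3, 3)
  iso <- data.frame(isolate_id = c("direct", "cultured"), source = "S1",
                    isolation_day = c(0, 5))
  calls <- classify_enrichment(rec, meta, iso)
  expect_equal(calls$summary$n_species, 2)
  expect_equal(calls$summary$n_post_enrichment, 1)
  expect_equal(calls$summary$frac_not_enriched, 1)  # 3 -> 3 is ratio 1
})

test_that("activity aggregation is sum-then-ratio and rank-consistent", {
  df <- tibble::tibble(feature_id = c("o1", "o2"), source = "S1", day = 0,
                       rna = c(5, 0), dna = c(1, 10))
  fx <- toy_paired(df)
  tax <- tibble::tibble(feature_id = c("o1", "o2"), family = "FamX")
  # OTU rank keeps per-feature ratios
  per_otu <- aggregate_activity(fx$rna, fx$dna, fx$meta, tax, rank = "otu")
  expect_equal(sort(per_otu$ratio), sort(c((5 + 1) / (1 + 1), (0 + 1) / (10 + 1))))
  # family rank: (5+0+1)/(1+10+1) = 0.5
  per_fam <- aggregate_activity(fx$rna, fx$dna, fx$meta, tax, rank = "family")
  expect_equal(per_fam$ratio, 0.5)
  expect_false(per_fam$active)
  # aggregation equals the ratio of rank-level marginal counts exactly
  expect_equal(per_fam$rna, sum(df$rna))
  expect_equal(per_fam$dna, sum(df$dna))
  # a (source, day) with a DNA library but no RNA partner is an error
  df2 <- dplyr::bind_rows(df, dplyr::mutate(df, day = 5))
  fx2 <- toy_paired(df2)
  rna_missing_day5 <- fx2$rna[, !grepl("d05", names(fx2$rna))]
  meta2 <- fx2$meta[!(fx2$meta$molecule == "RNA" & fx2$meta$day == 5), ]
  expect_error(aggregate_activity(rna_missing_day5, fx2$dna, meta2, tax,
                                  rank = "family"), "unpaired")
})

test_that("proportion of active taxa follows its definition", {
  df <- tibble::tibble(feature_id = sprintf("o%02d", 1:12), source = "S1",
                       day = 0,
                       rna = c(rep(30, 3), rep(1, 9)),
                       dna = c(rep(5, 3), rep(8, 9)))
  fx <- toy_paired(df)
  act <- aggregate_activity(fx$rna, fx$dna, fx$meta, rank = "otu")
  prop <- proportion_active(act)
  expect_equal(prop$prop_active[prop$source == "S1"], 3 / 12)
  # all ratios at or below 1 give zero
  df0 <- dplyr::mutate(df, rna = dna)
  fx0 <- toy_paired(df0)
  prop0 <- proportion_active(aggregate_activity(fx0$rna, fx0$dna, fx0$meta,
                                                rank = "otu"))
  expect_equal(prop0$prop_active[prop0$source == "S1"], 0)
})

test_that("a shrinking planted active set yields a decreasing proportion", {
  # deterministic scenario: 10 abundant taxa, the active set thins from
  # 6 to 2 across the time course, with strong RNA contrast
  days <- c(0, 12, 30)
  n_active <- c(6, 4, 2)
  df <- purrr::map_dfr(seq_along(days), function(k) {
    tibble::tibble(feature_id = sprintf("o%02d", 1:10), source = "S1",
                   day = days[k],
                   rna = c(rep(400, n_active[k]), rep(10, 10 - n_active[k])),
                   dna = rep(100, 10))
  })
  fx <- toy_paired(df)
  act <- aggregate_activity(fx$rna, fx$dna, fx$meta, rank = "otu")
  prop <- proportion_active(act) |> dplyr::filter(source == "S1")
  expect_equal(prop$prop_active, c(0.6, 0.4, 0.2))
  expect_true(all(diff(prop$prop_active) < 0))
})

test_that("planted active orders show positive median log ratios", {
  p <- sim_params(n_taxa = 60, depth = 8000)
  sim <- simulate_community(p, seed = 17, sequences = FALSE)
  act <- aggregate_activity(sim$counts_rna, sim$counts_dna, sim$meta,
                            rank = "otu") |>
    dplyr::inner_join(sim$truth$active, by = c(taxon = "feature_id", "day")) |>
    dplyr::filter(present, dna + rna > 20)
  med <- act |>
    dplyr::group_by(true_active) |>
    dplyr::summarise(m = median(log10_ratio), .groups = "drop")
  expect_gt(med$m[med$true_active], 0)
  expect_lt(med$m[!med$true_active], 0)
})
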