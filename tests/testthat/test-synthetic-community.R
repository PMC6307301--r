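test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(frac_r = 0.5, frac_k = 0.5, frac_inert = 0.5),
               "sum to 1")
  expect_error(sim_params(depth = 0), "positive")
  expect_error(sim_params(activity_factor_dormant = 2), "dormant")
  expect_error(sim_params(days = c(5, 12)), "day 0")
})

no_edges <- tibble::tibble(taxon_a = integer(), taxon_b = integer(),
                           sign = integer())

test_that("all-inert community has constant expected trajectories", {
  p <- sim_params(n_taxa = 20, frac_r = 0, frac_k = 0, frac_inert = 1,
                  planted_edges = no_edges)
  lat <- simulate_trajectories(p, seed = 3)
  spread <- lat |>
    dplyr::group_by(feature_id, source) |>
    dplyr::summarise(d = diff(range(expected)), .groups = "drop")
  expect_true(all(spread$d < 1e-12))
})

test_that("an r-strategist blooms at an interior day and collapses", {
  # exactly one r-strategist among inert background
  p <- sim_params(n_taxa = 20, frac_r = 0.05, frac_k = 0, frac_inert = 0.95,
                  planted_edges = no_edges)
  lat <- simulate_trajectories(p, seed = 11) |>
    dplyr::filter(feature_id == "otu001", source == "S1")
  e <- setNames(lat$expected, lat$day)
  expect_gt(max(e[c("5", "12", "21")]), e["0"])
  expect_gt(max(e[c("5", "12", "21")]), e["30"])
  # k-strategists grow monotonically in expectation (unnormalized growth
  # dominates an all-k community, where normalization is near-neutral)
  pk <- sim_params(n_taxa = 10, frac_r = 0, frac_k = 1, frac_inert = 0,
                   planted_edges = no_edges)
  latk <- simulate_trajectories(pk, seed = 4) |>
    dplyr::filter(source == "S1") |>
    dplyr::arrange(feature_id, day)
  # relative abundances always sum to 1
  sums <- simulate_trajectories(pk, seed = 4) |>
    dplyr::group_by(source, day) |>
    dplyr::summarise(s = sum(rel_abund), e = sum(expected), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
  expect_equal(sums$e, rep(1, nrow(sums)))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(n_taxa = 15, depth = 500, n_isolates = 2, seq_length = 120)
  s1 <- simulate_community(p, seed = 42)
  s2 <- simulate_community(p, seed = 42)
  expect_identical(s1$counts_dna, s2$counts_dna)
  expect_identical(s1$counts_rna, s2$counts_rna)
  expect_identical(s1$sequences$isolates, s2$sequences$isolates)
  s3 <- simulate_community(p, seed = 43)
  expect_false(identical(s1$counts_dna, s3$counts_dna))
})

test_that("library sizes are conserved exactly at the requested depth", {
  p <- sim_params(n_taxa = 30, depth = 1234)
  sim <- simulate_community(p, seed = 5, sequences = FALSE)
  expect_true(all(colSums(sim$counts_dna[, -1]) == 1234))
  expect_true(all(colSums(sim$counts_rna[, -1]) == 1234))
})

test_that("a single-taxon sample receives every read", {
  lat <- tibble::tibble(feature_id = "otuA", class = "inert", source = "S1",
                        day = 0, expected = 1, rel_abund = 1)
  out <- sample_counts(lat, depth = 1000, molecule = "DNA", seed = 1)
  expect_equal(out$counts[[2]], 1000)
  expect_error(sample_counts(lat, depth = 0, molecule = "DNA"), "positive")
})

test_that("RNA counts scale with the activity factor as specified", {
  # two taxa at 50/50; taxon A active with factor 4 against background 1:
  # expected RNA proportions 0.8 / 0.2, so the RNA:DNA count ratio for A
  # converges to 1.6 = 4 / (0.5 * 4 + 0.5 * 1)
  lat <- tibble::tibble(feature_id = c("A", "B"), class = "inert",
                        source = "S1", day = 0, expected = 0.5, rel_abund = 0.5)
  act <- tibble::tibble(feature_id = c("A", "B"), day = 0, factor = c(4, 1))
  ratios <- vapply(1:100, function(i) {
    rna <- sample_counts(lat, 2000, "RNA", activity = act, seed = i)$counts
    dna <- sample_counts(lat, 2000, "DNA", seed = 1000 + i)$counts
    rna[[2]][rna$feature_id == "A"] / dna[[2]][dna$feature_id == "A"]
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1.6), 3 * se + 1e-9)
})

test_that("isolates diverge from references by the binomial model", {
  # divergence 0 gives identical sequences
  s0 <- generate_sequences(2, seq_length = 200, isolate_divergence = 0, seed = 1)
  expect_identical(unname(s0$isolates["iso_otu001"]), unname(s0$references["otu001"]))
  expect_error(generate_sequences(2, isolate_divergence = 0.2), "0.05")
  # divergence 0.005 over 1400 nt: expected 7 substitutions
  nsub <- unlist(lapply(1:100, function(i) {
    generate_sequences(2, 1400, 0.005, seed = i)$isolate_map$n_substitutions
  }))
  se <- sqrt(1400 * 0.005 * 0.995 / length(nsub))
  expect_lt(abs(mean(nsub) - 7), 3 * se)
})

test_that("reference sequences are mutually below 97 percent identity", {
  s <- generate_sequences(2, seq_length = 800, seed = 9)
  expect_lt(pairwise_identity(s$references[1], s$references[2])$identity, 0.97)
})

test_that("dormant taxa recover ratios below 1 at depth and abundance", {
  # recovery property: dormant (factor 0.2) taxa at >= 1% abundance in
  # 10,000-read libraries should be called not active nearly always
  p <- sim_params(n_taxa = 50, depth = 1e4)
  hits <- unlist(lapply(1:10, function(s) {
    sim <- simulate_community(p, seed = s, sequences = FALSE)
    act <- aggregate_activity(sim$counts_rna, sim$counts_dna, sim$meta,
                              rank = "otu") |>
      dplyr::inner_join(sim$truth$active,
                        by = c(taxon = "feature_id", "day")) |>
      dplyr::inner_join(sim$latent |>
                          dplyr::select(feature_id, source, day, rel_abund),
                        by = c(taxon = "feature_id", "source", "day")) |>
      dplyr::filter(!true_active, rel_abund >= 0.01)
    act$ratio < 1
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("written community files round-trip through the readers", {
  p <- sim_params(n_taxa = 12, depth = 300, n_isolates = 3, seq_length = 150)
  sim <- simulate_community(p, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_community(sim, dir)
  counts <- read_counts(paths["counts_dna"])
  expect_equal(counts, sim$counts_dna, ignore_attr = TRUE)
  md <- read_sample_metadata(paths["meta"])
  expect_setequal(md$sample_id, sim$meta$sample_id)
  tax <- read_taxonomy(paths["taxonomy"])
  expect_equal(tax$family, sim$taxonomy$family)
  seqs <- read_fasta(paths["references"])
  expect_identical(unname(seqs), unname(sim$sequences$references))
})
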