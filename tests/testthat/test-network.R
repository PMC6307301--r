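test_that("the prevalence and abundance filters use the stated boundaries", {
  m <- matrix(5, nrow = 4, ncol = 15)
  m[1, 1:3] <- 0                       # 3 zeros of 15 -> removed
  m[2, 1:2] <- 0                       # exactly 2 zeros, total 65 -> kept
  m[3, ] <- c(1, rep(0, 14))           # total 1 -> removed (floor is > 1)
  m[4, 1] <- 0; m[4, 2] <- 2; m[4, 3:15] <- 0  # 14 zeros -> removed
  counts <- toy_counts(m)
  kept <- filter_features(counts)
  expect_equal(kept$feature_id, "f02")
  expect_warning(filter_features(toy_counts(matrix(c(1, 0, 0), ncol = 3))),
                 "removed")
  expect_error(filter_features(toy_counts(matrix(1:4, 2))), "3 samples")
})

test_that("a perfect log-linear pair makes a positive unit edge", {
  k <- 1:15
  m <- rbind(3 * 10^k, 7 * 10^k)
  net <- build_network(toy_counts(m))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$r, 1)
  expect_equal(net$edges$sign, "positive")
  expect_equal(net$edges$n_pairs, 15L)
})

test_that("edges match the exhaustive all-pairs oracle", {
  withr::with_seed(12, {
    for (rep in 1:3) {
      m <- matrix(rpois(30 * 15, lambda = 40), nrow = 30)
      m[sample(length(m), 40)] <- 0
      counts <- filter_features(toy_counts(m), max_zeros = 4)
      net <- build_network(counts, threshold = 0.7, min_pairs = 9)
      want <- oracle_edges(counts, threshold = 0.7, min_pairs = 9)
      got <- net$edges[order(net$edges$feature_a, net$edges$feature_b), ]
      want <- want[order(want$feature_a, want$feature_b), ]
      expect_equal(got$feature_a, want$feature_a)
      expect_equal(got$feature_b, want$feature_b)
      expect_equal(got$r, want$r, tolerance = 1e-12)
    }
  })
})

test_that("a sub-threshold correlation yields no edge", {
  # two features engineered to correlate just below 0.7 on log counts
  withr::with_seed(33, {
    repeat {
      x <- rpois(15, 50) + 1
      y <- round(x * runif(15, 0.3, 3)) + 1
      r <- cor(log10(x), log10(y))
      if (r > 0.6 && r < 0.695) break
    }
  })
  counts <- toy_counts(rbind(x, y))
  net <- build_network(counts, threshold = 0.7)
  expect_equal(nrow(net$edges), 0)
  # the same table passes at a threshold below its r
  net2 <- build_network(counts, threshold = 0.5)
  expect_equal(nrow(net2$edges), 1)
})

test_that("raising the threshold never adds edges", {
  withr::with_seed(13, {
    m <- matrix(rpois(20 * 15, lambda = 30) + 1, nrow = 20)
  })
  counts <- toy_counts(m)
  ths <- c(0.3, 0.5, 0.7, 0.9)
  sizes <- vapply(ths, function(t) nrow(build_network(counts, t)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
  edges_hi <- build_network(counts, 0.9)$edges
  edges_lo <- build_network(counts, 0.3)$edges
  expect_true(all(paste(edges_hi$feature_a, edges_hi$feature_b) %in%
                    paste(edges_lo$feature_a, edges_lo$feature_b)))
})

test_that("power-of-10 rescaling of features or the table preserves edges", {
  # log10 turns multiplicative scaling into an additive shift of a
  # feature's whole vector, which Pearson ignores
  withr::with_seed(14, {
    m <- matrix(rpois(12 * 15, lambda = 25) + 1, nrow = 12)
  })
  net1 <- build_network(toy_counts(m))
  m2 <- m; m2[3, ] <- m2[3, ] * 100; m2[9, ] <- m2[9, ] * 10
  net2 <- build_network(toy_counts(m2))
  expect_equal(net1$edges, net2$edges, tolerance = 1e-12)
  net3 <- build_network(toy_counts(m * 1000))
  expect_equal(net1$edges, net3$edges, tolerance = 1e-12)
})

test_that("sparse pairs are skipped, not turned into edges", {
  m <- rbind(c(10, 100, 1000, rep(0, 12)),
             c(20, 200, 2000, rep(0, 12)),
             rep(50, 15))
  net <- build_network(toy_counts(m), min_pairs = 9)
  expect_equal(nrow(net$edges), 0)
  expect_gte(nrow(net$skipped), 1)
})

test_that("false-edge rate on independent noise matches a permutation null", {
  # independent multinomial counts: any edge is a false positive; the
  # observed rate should match the rate on column-permuted (null) data
  withr::with_seed(15, {
    rate <- function(m) {
      counts <- filter_features(toy_counts(m), max_zeros = 15)
      ed <- nrow(build_network(counts, threshold = 0.7, min_pairs = 9)$edges)
      n <- nrow(counts)
      ed / (n * (n - 1) / 2)
    }
    obs <- null <- numeric(10)
    for (i in 1:10) {
      m <- rmultinom(15, 3000, prob = rep(1 / 60, 60))
      obs[i] <- rate(m)
      null[i] <- rate(t(apply(m, 1, sample)))
    }
    # both rates are tiny and statistically indistinguishable
    expect_lt(abs(mean(obs) - mean(null)),
              3 * sqrt(var(obs) / 10 + var(null) / 10) + 0.005)
  })
})

test_that("group associations vote by sign with ties reported mixed", {
  tax <- tibble::tibble(feature_id = sprintf("f%02d", 1:6),
                        family = rep(c("FamA", "FamB"), each = 3))
  net <- structure(list(
    nodes = tibble::tibble(feature_id = tax$feature_id,
                           n_samples_nonzero = 15L),
    edges = tibble::tibble(
      feature_a = c("f01", "f02", "f01", "f02"),
      feature_b = c("f04", "f05", "f05", "f04"),
      r = c(0.9, 0.8, -0.8, -0.9),
      sign = c("positive", "positive", "negative", "negative"),
      n_pairs = 15L),
    skipped = tibble::tibble(), params = list(threshold = 0.7, min_pairs = 9)),
    class = "co_network")
  assoc <- group_associations(net, tax)
  ab <- assoc[assoc$group_a == "FamA" & assoc$group_b == "FamB", ]
  expect_equal(ab$n_pos, 2L)
  expect_equal(ab$n_neg, 2L)
  expect_equal(ab$net_sign, "mixed")
  # dropping one negative edge flips the vote to positive
  net$edges <- net$edges[-4, ]
  assoc2 <- group_associations(net, tax)
  expect_equal(assoc2$net_sign[assoc2$group_a == "FamA"], "positive")
  # unclassified nodes group under "unclassified"
  net$edges$feature_b[1] <- "f99"
  net$nodes <- rbind(net$nodes, tibble::tibble(feature_id = "f99",
                                               n_samples_nonzero = 15L))
  assoc3 <- group_associations(net, tax)
  expect_true("unclassified" %in% c(assoc3$group_a, assoc3$group_b))
})

test_that("graph exports round-trip the edge set", {
  k <- 1:15
  m <- rbind(3 * 10^k, 7 * 10^k, rep(c(1, 5), length.out = 15))
  net <- build_network(toy_counts(m), threshold = 0.9)
  g <- as_igraph(net)
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gsize(g2), nrow(net$edges))
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
})
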