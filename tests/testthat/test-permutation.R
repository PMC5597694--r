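test_that("perm test degenerates correctly and respects the p floor", {
  # two groups with identical per-individual content: delta = 0, p = 1
  set.seed(5)
  pairs <- lapply(1:4, function(i) random_seqs(2, 60))
  g1 <- manual_matrix(pairs, prefix = "a")
  g2 <- manual_matrix(pairs, prefix = "b")
  pt <- perm_test(g1, g2, n_perm = 200, seed = 1)
  expect_equal(pt$observed_delta, 0)
  expect_equal(pt$p, 1)

  # observed exceeding every random delta gives p = 1/N
  g3 <- manual_matrix(lapply(1:3, function(i) c(strrep("A", 60), strrep("A", 60))),
                      prefix = "mono")
  g4 <- manual_matrix(lapply(1:3, function(i) random_seqs(2, 60)), prefix = "div")
  # impossible here to always beat every permutation, so assert the floor
  pt2 <- perm_test(g3, g4, n_perm = 100, seed = 2)
  expect_gte(pt2$p, 1 / 100)
  expect_lte(pt2$p, 1)

  expect_error(perm_test(g1, g1, n_perm = 10), "disjoint")
})

test_that("perm test is bit-reproducible under a fixed seed", {
  gr <- ratio_groups(seed = 31, ratio = 0.5, n = 6)
  p1 <- perm_test(gr$g1, gr$g2, n_perm = 500, seed = 11)
  p2 <- perm_test(gr$g1, gr$g2, n_perm = 500, seed = 11)
  expect_identical(p1$p, p2$p)
  expect_identical(p1$observed_delta, p2$observed_delta)
})

test_that("exhaustive enumeration uses the full partition space", {
  set.seed(8)
  g1 <- manual_matrix(lapply(1:2, function(i) random_seqs(2, 50)), prefix = "x")
  g2 <- manual_matrix(lapply(1:2, function(i) random_seqs(2, 50)), prefix = "y")
  ex <- exhaustive_test(g1, g2)
  expect_equal(ex$n_partitions, choose(4, 2))
  expect_gte(ex$p, 1 / 6)

  # identical per-individual multisets: every partition ties, p = 1
  pairs <- lapply(1:2, function(i) c(strrep("ACGT", 10), strrep("TGCA", 10)))
  h1 <- manual_matrix(pairs, prefix = "u")
  h2 <- manual_matrix(pairs, prefix = "v")
  expect_equal(exhaustive_test(h1, h2)$p, 1)

  big1 <- manual_matrix(lapply(1:12, function(i) random_seqs(2, 10)), prefix = "b")
  big2 <- manual_matrix(lapply(1:12, function(i) random_seqs(2, 10)), prefix = "c")
  expect_error(exhaustive_test(big1, big2), "exceeds")
})

test_that("Monte-Carlo p converges to the exact exhaustive p", {
  # moderate-size check; the acceptance suite runs the full 20-instance one
  for (seed in c(101, 202)) {
    gr <- ratio_groups(seed = seed, ratio = 0.4, n = 3, K = 6)
    ex <- exhaustive_test(gr$g1, gr$g2)
    mc <- perm_test(gr$g1, gr$g2, n_perm = 20000, seed = seed + 1)
    sd_mc <- sqrt(ex$p * (1 - ex$p) / 20000)
    expect_lt(abs(mc$p - ex$p), max(3 * sd_mc, 3 / 20000))
  }
})

test_that("Bonferroni uses alpha/n with an inclusive threshold", {
  b <- bonferroni(c(0.002, 0.0021, 0.05), alpha = 0.05, n_tests = 25)
  expect_equal(unique(b$alpha_adjusted), 0.002)
  expect_identical(b$significant, c(TRUE, FALSE, FALSE))

  # single test: threshold is alpha itself
  b1 <- bonferroni(0.04, alpha = 0.05)
  expect_true(b1$significant)

  # a p computed as a permutation proportion compares correctly
  expect_true(bonferroni(20 / 10000, alpha = 0.05, n_tests = 25)$significant)
})

test_that("permutation_scan derives stable per-test seeds and a manifest", {
  cfg <- two_taxon_scenario(seed = 77)
  ds <- simulate_dataset(cfg)
  base <- c("A", "B")
  comparisons <- data.frame(locus1 = paste0("SimHi-", base),
                            locus2 = paste0("SimLo-", base),
                            taxa1 = "taxonHi", taxa2 = "taxonLo",
                            stringsAsFactors = FALSE)
  sc <- permutation_scan(ds$genotypes, ds$sequences, comparisons, ds$models,
                         n_perm = 299, seed = 5)
  expect_equal(nrow(sc$results), 2)
  expect_equal(sc$manifest$n_tests, 2)
  # adding a test leaves earlier p-values untouched
  comparisons3 <- rbind(comparisons,
                        data.frame(locus1 = "SimHi-C", locus2 = "SimLo-C",
                                   taxa1 = "taxonHi", taxa2 = "taxonLo"))
  sc3 <- permutation_scan(ds$genotypes, ds$sequences, comparisons3, ds$models,
                          n_perm = 299, seed = 5)
  expect_identical(sc3$results$p[1:2], sc$results$p)
})
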