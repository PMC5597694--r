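test_that("pools are distinct, functional and seed-reproducible", {
  model <- pan_gene_model("B")
  rates <- default_region_rates(model, "AB")
  p1 <- generate_pool(model, 8, rates, seed = 1)
  p2 <- generate_pool(model, 8, rates, seed = 1)
  expect_identical(p1$sequences, p2$sequences)
  expect_equal(length(unique(p1$sequences)), 8)
  expect_true(all(vapply(p1$sequences, is_functional_allele, logical(1),
                         model = model)))
  expect_true(all(nchar(p1$sequences) == model_length(model)))
  expect_false(any(grepl("-", p1$sequences, fixed = TRUE)))

  # zero rates: only a single-allele pool is possible
  expect_equal(length(generate_pool(model, 1, 0, seed = 2)$sequences), 1)
  expect_error(generate_pool(model, 3, 0, seed = 2, max_tries = 10),
               "increase region_rates")
})

test_that("pool allele names parse and encode protein/coding classes", {
  model <- pan_gene_model("A")
  pool <- generate_pool(model, 10, default_region_rates(model, "AB"),
                        seed = 4, locus = "Sim-A")
  nm <- names(pool$sequences)
  for (s in nm) expect_silent(parse_allele_name(s))
  expect_identical(collapse_name(nm, "full"), nm)

  # names sharing the coding truncation share the CDS, and vice versa
  cds <- vapply(pool$sequences,
                function(s) extract_cds(s, model)$nucleotides, character(1))
  cod_names <- collapse_name(nm, "coding")
  expect_equal(length(unique(cod_names)), length(unique(cds)))
  expect_true(all(tapply(cds, cod_names, function(x) length(unique(x))) == 1))

  prot <- vapply(cds, function(x) translate_cds(x)$protein, character(1))
  prot_names <- collapse_name(nm, "protein")
  expect_equal(length(unique(prot_names)), length(unique(prot)))
})

test_that("sampled genotypes resolve against the pool and respect n", {
  model <- pan_gene_model("C")
  pool <- generate_pool(model, 6, default_region_rates(model, "C"), seed = 6)
  sg <- sample_genotypes(pool, 20, "taxon1", seed = 7)
  gt <- sg$genotypes
  expect_equal(length(unique(gt$individual)), 20)
  expect_equal(nrow(genotype_calls(gt)), 40)
  expect_true(all(genotype_calls(gt)$allele %in% names(pool$sequences)))

  # single-allele pool: every individual homozygous, pi = 0
  pool1 <- generate_pool(model, 1, 0, seed = 8)
  sg1 <- sample_genotypes(pool1, 5, "t", seed = 9)
  sm <- build_matrix(sg1$genotypes, pool1$sequences, pool1$locus, model)
  expect_equal(nucleotide_diversity(sm)$pi, 0)

  # frequencies are reproducible under the seed
  sg_a <- sample_genotypes(pool, 5, "t", freq_concentration = 0.4, seed = 33)
  sg_b <- sample_genotypes(pool, 5, "t", freq_concentration = 0.4, seed = 33)
  expect_identical(sg_a$freqs, sg_b$freqs)
})

test_that("expected pi scales with diversity_scale", {
  model <- pan_gene_model("B")
  rates <- default_region_rates(model, "AB")
  anc <- panmhc:::make_ancestral(model, seed = 11)
  f <- rep(1 / 10, 10)
  p_hi <- generate_pool(model, 10, rates, seed = 12, ancestral = anc)
  p_lo <- generate_pool(model, 10, rates, seed = 13, ancestral = anc,
                        diversity_scale = 0.3)
  r <- expected_pi(p_lo, f) / expected_pi(p_hi, f)
  # substitutions are rare enough that expected pi is ~linear in the rate
  expect_gt(r, 0.15); expect_lt(r, 0.5)
})

test_that("datasets are deterministic and internally consistent", {
  cfg <- two_taxon_scenario(seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(two_taxon_scenario(seed = 99))
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(as.data.frame(d1$genotypes), as.data.frame(d2$genotypes))

  # every genotype call resolves to a sequence
  calls <- genotype_calls(d1$genotypes)
  expect_true(all(calls$allele %in% names(d1$sequences)))

  # truth record holds an expectation for every taxon x locus
  expect_equal(length(d1$truth), 6)
  expect_true(all(vapply(d1$truth, function(t) t$expected_pi_exons,
                         numeric(1)) > 0))
})

test_that("sample pi recovers the generator expectation", {
  model <- pan_gene_model("B")
  rates <- default_region_rates(model, "AB")
  errs <- vapply(1:30, function(i) {
    pool <- generate_pool(model, 8, rates, seed = 1000 + i)
    sg <- sample_genotypes(pool, 10, "t", seed = 2000 + i)
    sm <- build_matrix(sg$genotypes, pool$sequences, pool$locus, model)
    nucleotide_diversity(sm)$pi - expected_pi(pool, sg$freqs)
  }, numeric(1))
  # mean deviation within 3 standard errors of zero
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)))
})

test_that("artifact injection follows the configured rate and is truthful", {
  model <- pan_gene_model("B")
  pool <- generate_pool(model, 8, default_region_rates(model, "AB"), seed = 55)
  sg <- sample_genotypes(pool, 25, "t", seed = 56)

  # rate 0: all replicate pairs concordant
  inj0 <- inject_artifacts(sg$genotypes, pool$sequences, model, pool$locus,
                           artifact_rate = 0, seed = 57)
  expect_false(any(inj0$truth$artifact))
  qc0 <- qc_scan(inj0$calls, model)
  expect_true(all(qc0$status == "concordant"))

  # rate 1: every heterozygote yields a discordant pair
  inj1 <- inject_artifacts(sg$genotypes, pool$sequences, model, pool$locus,
                           artifact_rate = 1, seed = 58)
  gt <- sg$genotypes
  het <- !is.na(gt$allele2)
  expect_equal(sum(inj1$truth$artifact), sum(het))
  # every injected artifact fails the functional check by construction
  for (ind in inj1$truth$individual[inj1$truth$artifact]) {
    pair <- inj1$calls[[ind]]
    sol <- c(pair$r1$alleles, pair$r2$alleles)
    sol <- sol[grepl("artifact", names(sol))]
    expect_false(is_functional_allele(sol[[1]], model))
  }
})
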