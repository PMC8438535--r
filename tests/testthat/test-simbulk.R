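test_that("configuration objects validate their invariants", {
  expect_error(genome_map(c(chr1 = -5)), "positive")
  expect_error(genome_map(c(5e6, 5e6)), "names")
  expect_error(genome_map(c(a = 1e6, a = 2e6)), "unique")
  expect_error(genome_map(c(a = 1e6), cm_per_mb = -1), "non-negative")
  expect_error(seq_config(mean_depth = 0), "positive")
  expect_error(seq_config(error_rate = 0.5), "0.5")
  expect_error(cross_config(n_f2 = 0), "at least 1")
  expect_error(cross_config(sites_per_chrom = 0), "at least 1")
  g <- genome_map(c(chr1 = 1e6))
  expect_error(
    simulate_f2_population(g, cross_config(causal_chrom = "chr9")),
    "chr9")
  expect_error(
    simulate_f2_population(g, cross_config(causal_chrom = "chr1",
                                           causal_pos = 2e6)),
    "exceeds")
})

test_that("F2 segregation follows the Mendelian 3:1 expectation", {
  set.seed(101)
  g <- genome_map(c(chr1 = 2e6))
  cr <- cross_config(n_f2 = 2000, causal_chrom = "chr1", causal_pos = 1e6,
                     sites_per_chrom = 5)
  pop <- simulate_f2_population(g, cr)
  frac <- mean(pop$fertile)
  band <- 3 * sqrt(0.75 * 0.25 / 2000)
  expect_gt(frac, 0.75 - band)
  expect_lt(frac, 0.75 + band)
})

test_that("phenotype obeys the dominant single-gene rule", {
  set.seed(7)
  pop <- simulate_f2_population(tiny_genome(), tiny_cross())
  causal <- which(pop$sites$causal)
  expect_length(causal, 1L)
  expect_identical(pop$fertile, pop$genotypes[, causal] >= 1L)
  expect_true(all(pop$genotypes %in% 0:2))
  expect_identical(pop$genotypes, pop$gam1 + pop$gam2)
})

test_that("sites at zero map distance are always co-inherited", {
  set.seed(13)
  gam <- bsascan:::sim_gametes_chrom(2000, c(7, 7), chrom_cm = 40)
  expect_identical(gam[, 1], gam[, 2])
})

test_that("recombinant fraction recovers the Haldane map distance", {
  # map distance chosen so the expected recombinant fraction is 0.10
  d_cm <- -50 * log(1 - 2 * 0.10)
  set.seed(5)
  gam <- bsascan:::sim_gametes_chrom(5000, c(0, d_cm), chrom_cm = 40)
  c_hat <- mean(gam[, 1] != gam[, 2])
  expect_gte(c_hat, 0.08)
  expect_lte(c_hat, 0.12)
})

test_that("bulks have the configured sizes and the right phenotypes", {
  set.seed(3)
  pop <- simulate_f2_population(tiny_genome(), tiny_cross())
  b <- make_bulks(pop)
  expect_length(b$fertile, 37L)
  expect_length(b$sterile, 38L)
  expect_length(intersect(b$fertile, b$sterile), 0L)
  expect_true(all(pop$fertile[b$fertile]))
  expect_false(any(pop$fertile[b$sterile]))
  # every sterile-bulk plant is homozygous non-restorer at the causal site
  causal <- which(pop$sites$causal)
  expect_true(all(pop$genotypes[b$sterile, causal] == 0L))
  expect_error(make_bulks(pop, n_fertile = nrow(pop$genotypes) + 1),
               "increase `n_f2`")
})

test_that("fertile-bulk causal allele frequency converges to 2/3", {
  # 1/3 of fertile F2 plants are homozygous and 2/3 heterozygous for the
  # restorer allele, so the bulk frequency has expectation 2/3
  g <- genome_map(c(chr1 = 2e6))
  cr <- cross_config(n_f2 = 300, causal_chrom = "chr1", causal_pos = 1e6,
                     site_positions = list(chr1 = 1e6))
  set.seed(99)
  freqs <- replicate(10000, {
    pop <- simulate_f2_population(g, cr)
    b <- make_bulks(pop)
    bulk_allele_freq(pop, b$fertile)[1]
  })
  expect_gte(mean(freqs), 0.64)
  expect_lte(mean(freqs), 0.70)
})

test_that("pooled reads follow the frequency-plus-error model", {
  set.seed(17)
  # restorer frequency 0 in the sterile bulk: no ALT reads without error
  pop <- simulate_f2_population(tiny_genome(), tiny_cross())
  b <- make_bulks(pop)
  sites <- simulate_pool_reads(pop, b, seq_config(mean_depth = 80,
                                                  error_rate = 0))
  causal <- which(attr(sites, "truth")$causal)
  expect_identical(sites$s_alt[causal], 0L)
  # pool frequency 1 with error 0.01: mean ALT fraction 0.99 over 10k sites
  pop1 <- all_restorer_population(10, 10000)
  bulks1 <- structure(list(fertile = 1:5, sterile = 6:10),
                      class = "bsa_bulks")
  s1 <- simulate_pool_reads(pop1, bulks1,
                            seq_config(mean_depth = 60, error_rate = 0.01))
  frac <- with(s1, sum(f_alt) / sum(f_alt + f_ref))
  expect_gte(frac, 0.985)
  expect_lte(frac, 0.995)
})

test_that("truth sidecar matches the bulk genotypes", {
  ex <- tiny_experiment(seed = 23)
  truth <- attr(ex$sites, "truth")
  expect_equal(truth$f_freq, bulk_allele_freq(ex$pop, ex$bulks$fertile))
  expect_equal(truth$s_freq, bulk_allele_freq(ex$pop, ex$bulks$sterile))
  expect_identical(truth$causal, ex$pop$sites$causal)
  # sterile bulk carries no restorer allele at the causal locus
  expect_identical(truth$s_freq[truth$causal], 0)
})

test_that("delta at unlinked sites is centred on zero", {
  g <- genome_map(c(chr1 = 2e6, chr2 = 2e7), cm_per_mb = 2)
  set.seed(11)
  deltas <- unlist(lapply(1:5, function(i) {
    cr <- cross_config(n_f2 = 300, causal_chrom = "chr1", causal_pos = 1e6,
                       sites_per_chrom = 200)
    pop <- simulate_f2_population(g, cr)
    b <- make_bulks(pop)
    s <- compute_indices(
      simulate_pool_reads(pop, b, seq_config(mean_depth = 100)))
    s$delta[s$chrom == "chr2"]
  }))
  expect_gte(length(deltas), 1000L)
  expect_lt(abs(mean(deltas)), 0.05)
})

test_that("reference-parent conventions orient the ALT allele correctly", {
  ex <- tiny_experiment(seed = 31)
  truth <- attr(ex$sites, "truth")
  causal <- which(truth$causal)
  s <- compute_indices(ex$sites)
  # reference = sterile parent: ALT is the restorer allele, so the fertile
  # pool is ALT-enriched at the causal site and the sterile pool is not
  expect_gt(s$f_index[causal], 0.5)
  expect_lt(s$s_index[causal], 0.1)
  # reference = restorer parent flips both indices
  set.seed(31)
  s2 <- compute_indices(
    simulate_pool_reads(ex$pop, ex$bulks,
                        seq_config(mean_depth = 60, error_rate = 0.005,
                                   ref_parent = "restorer")))
  expect_lt(s2$f_index[causal], 0.5)
  expect_gt(s2$s_index[causal], 0.9)
})

test_that("explicit site positions are honoured and the causal site added", {
  set.seed(41)
  g <- genome_map(c(chr1 = 1e6, chr2 = 1e6))
  cr <- cross_config(n_f2 = 50, causal_chrom = "chr1", causal_pos = 5e5,
                     site_positions = list(chr1 = c(1e5, 9e5)))
  pop <- simulate_f2_population(g, cr)
  expect_identical(pop$sites$pos, c(1e5, 5e5, 9e5))
  expect_identical(pop$sites$chrom, rep("chr1", 3))
  expect_error(
    simulate_f2_population(g, cross_config(
      n_f2 = 50, causal_chrom = "chr1", causal_pos = 5e5,
      site_positions = list(chr1 = 2e6))),
    "outside")
})
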