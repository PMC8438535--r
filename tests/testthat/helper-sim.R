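# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures beyond what make_fixture() writes at test time.

tiny_genome <- function() genome_map(c(chr1 = 2e6, chr2 = 2e6), cm_per_mb = 2)

tiny_cross <- function(...) {
  cross_config(n_f2 = 300, causal_chrom = "chr1", causal_pos = 1e6,
               sites_per_chrom = 50, ...)
}

tiny_experiment <- function(seed = 1, depth = 60, error = 0.005) {
  simulate_bsa_experiment(tiny_genome(), tiny_cross(),
                          seq_config(mean_depth = depth, error_rate = error),
                          seed = seed)
}

# random indexed site table on one chromosome (no simulation machinery)
random_indexed_sites <- function(n, chrom = "chrZ", max_pos = 1e7,
                                 depth = 50L) {
  pos <- as.numeric(sort(sample.int(max_pos, n)))
  f_alt <- stats::rbinom(n, depth, stats::runif(n))
  s_alt <- stats::rbinom(n, depth, stats::runif(n))
  variant_class <- sample(c("SNP", "InDel"), n, replace = TRUE)
  sites <- data.frame(
    chrom = rep(chrom, n), pos = pos,
    ref_allele = rep("A", n),
    alt_allele = ifelse(variant_class == "InDel", "TT", "T"),
    variant_class = variant_class,
    f_ref = depth - f_alt, f_alt = f_alt,
    s_ref = depth - s_alt, s_alt = s_alt,
    stringsAsFactors = FALSE)
  compute_indices(sites)
}

# a degenerate population where every plant is homozygous for the restorer
# allele at every site; exercises the read sampler at pool frequency 1
all_restorer_population <- function(n_plants, n_sites) {
  sites <- data.frame(chrom = rep("chr1", n_sites),
                      pos = seq_len(n_sites) * 100,
                      causal = c(TRUE, rep(FALSE, n_sites - 1L)),
                      stringsAsFactors = FALSE)
  sites$cm <- sites$pos / 1e6 * 2
  geno <- matrix(2L, n_plants, n_sites)
  structure(list(sites = sites,
                 gam1 = matrix(1L, n_plants, n_sites),
                 gam2 = matrix(1L, n_plants, n_sites),
                 genotypes = geno,
                 fertile = rep(TRUE, n_plants),
                 cross = cross_config(n_f2 = n_plants, causal_chrom = "chr1",
                                      causal_pos = 100,
                                      n_fertile_bulk = min(n_plants, 5),
                                      n_sterile_bulk = 1)),
            class = "f2_population")
}
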