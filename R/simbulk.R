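# Simulation of F2 bulked-segregant sequencing experiments.
#
# The model: a cross between a cytoplasmic-male-sterile (CMS) parent and a
# restorer parent carrying a single dominant restorer allele. F1 plants are
# selfed; an F2 plant is fertile iff it carries >= 1 restorer allele at the
# causal locus. Extreme-phenotype bulks are pooled and sequenced at variant
# sites where the parental haplotypes differ, yielding per-pool allele depths.

#' Define a genome map for simulation
#'
#' A genome map lists the chromosomes (name and physical length) and a single
#' scalar converting physical to genetic distance. The default is a desk-scale
#' genome of four 20-Mb chromosomes, small enough that a full simulated scan
#' runs in seconds while retaining one causal and several unlinked
#' chromosomes.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in base
#'   pairs. Names are chromosome identifiers and must be unique; lengths must
#'   be strictly positive.
#' @param cm_per_mb Recombination rate, centimorgans per megabase
#'   (non-negative). The default 2 cM/Mb is a typical plant genome-wide
#'   average.
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes` (named numeric vector, bp) and `cm_per_mb`.
#' @examples
#' genome_map(c(chrA = 5e6, chrB = 5e6), cm_per_mb = 2)
#' @export
genome_map <- function(chromosomes = c(A09 = 2e7, A10 = 2e7, C03 = 2e7, C04 = 2e7),
                       cm_per_mb = 2) {
  if (length(chromosomes) == 0L || !is.numeric(chromosomes)) {
    stop("`chromosomes` must be a non-empty named numeric vector of lengths", call. = FALSE)
  }
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)) ||
      any(!nzchar(names(chromosomes)))) {
    stop("chromosome names must be present and unique", call. = FALSE)
  }
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0)) {
    stop("chromosome lengths must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1L || !is.finite(cm_per_mb) ||
      cm_per_mb < 0) {
    stop("`cm_per_mb` must be a single non-negative number", call. = FALSE)
  }
  structure(list(chromosomes = chromosomes, cm_per_mb = cm_per_mb),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", length(x$chromosomes), " chromosomes, ",
      format(sum(x$chromosomes) / 1e6, digits = 4), " Mb total, ",
      x$cm_per_mb, " cM/Mb\n", sep = "")
  invisible(x)
}

#' Configure the F2 cross and bulk construction
#'
#' Defaults mirror the mapping experiment the package emulates: bulks of 37
#' extremely fertile and 38 extremely sterile F2 plants, with variant sites
#' dense along every chromosome. `n_f2 = 300` keeps the sterile class (a
#' quarter of the population in expectation) comfortably above the bulk size.
#'
#' @param n_f2 Number of F2 plants to simulate.
#' @param causal_chrom Chromosome carrying the causal restorer locus.
#' @param causal_pos 1-based position (bp) of the causal locus.
#' @param n_fertile_bulk,n_sterile_bulk Bulk sizes (defaults 37 and 38).
#' @param sites_per_chrom Number of variant sites simulated per chromosome
#'   (the causal site is added on top on `causal_chrom`).
#' @param site_positions Optional named list (chromosome -> numeric vector
#'   of 1-based positions) fixing the variant sites explicitly instead of
#'   placing `sites_per_chrom` sites uniformly at random; chromosomes absent
#'   from the list get no sites. The causal site is still inserted.
#' @param prop_indel Proportion of sites classed as InDels rather than SNPs;
#'   the default reflects the roughly 1:2 SNP:InDel balance seen in
#'   resequencing of diverged Brassica parents.
#' @return An object of class `cross_config` (a named list).
#' @export
cross_config <- function(n_f2 = 300, causal_chrom = "A09", causal_pos = 1e7,
                         n_fertile_bulk = 37, n_sterile_bulk = 38,
                         sites_per_chrom = 500, prop_indel = 0.67,
                         site_positions = NULL) {
  if (!is.null(site_positions) &&
      (!is.list(site_positions) || is.null(names(site_positions)))) {
    stop("`site_positions` must be a named list of position vectors",
         call. = FALSE)
  }
  for (nm in c("n_f2", "causal_pos", "n_fertile_bulk", "n_sterile_bulk",
               "sites_per_chrom")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != trunc(v)) {
      stop("`", nm, "` must be a single whole number", call. = FALSE)
    }
  }
  if (n_f2 < 1) stop("`n_f2` must be at least 1", call. = FALSE)
  if (causal_pos < 1) stop("`causal_pos` must be >= 1", call. = FALSE)
  if (sites_per_chrom < 1) stop("`sites_per_chrom` must be at least 1", call. = FALSE)
  if (n_fertile_bulk < 1 || n_sterile_bulk < 1) {
    stop("bulk sizes must be at least 1", call. = FALSE)
  }
  if (!is.numeric(prop_indel) || prop_indel < 0 || prop_indel > 1) {
    stop("`prop_indel` must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_f2 = as.integer(n_f2), causal_chrom = causal_chrom,
                 causal_pos = as.numeric(causal_pos),
                 n_fertile_bulk = as.integer(n_fertile_bulk),
                 n_sterile_bulk = as.integer(n_sterile_bulk),
                 sites_per_chrom = as.integer(sites_per_chrom),
                 prop_indel = prop_indel,
                 site_positions = site_positions),
            class = "cross_config")
}

#' Configure pooled-sequencing read sampling
#'
#' Read depth at each site in each pool is Poisson with mean `mean_depth`;
#' the count of reads carrying the non-reference allele is binomial with
#' success probability `f * (1 - error_rate) + (1 - f) * error_rate`, where
#' `f` is the pool frequency of the non-reference allele. `ref_parent`
#' chooses which parental haplotype plays the reference-genome role:
#' `"sterile"` (the CMS parent everywhere, the default), `"restorer"`, or
#' `"random"` (an independent uniform choice per site, emulating a reference
#' genome that is a mosaic of the two parental states).
#'
#' @param mean_depth Expected reads per site per pool. Either a single value
#'   or a length-2 vector `c(F_pool, S_pool)` for unequal pool depths.
#' @param error_rate Per-read allele-flip probability, in `[0, 0.5)`.
#' @param ref_parent `"sterile"`, `"restorer"` or `"random"`.
#' @return An object of class `seq_config` (a named list).
#' @export
seq_config <- function(mean_depth = 60, error_rate = 0.005,
                       ref_parent = c("sterile", "restorer", "random")) {
  ref_parent <- match.arg(ref_parent)
  if (!is.numeric(mean_depth) || !length(mean_depth) %in% c(1L, 2L) ||
      any(!is.finite(mean_depth)) || any(mean_depth <= 0)) {
    stop("`mean_depth` must be one or two positive numbers", call. = FALSE)
  }
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 0.5) {
    stop("`error_rate` must lie in [0, 0.5)", call. = FALSE)
  }
  if (length(mean_depth) == 1L) mean_depth <- rep(mean_depth, 2L)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 ref_parent = ref_parent),
            class = "seq_config")
}

# Place variant sites on the genome. Positions are uniform without
# replacement per chromosome; the causal position is inserted (if absent) on
# the causal chromosome and flagged.
place_sites <- function(genome, cross) {
  if (!cross$causal_chrom %in% names(genome$chromosomes)) {
    stop("causal chromosome '", cross$causal_chrom, "' is not in the genome map",
         call. = FALSE)
  }
  if (cross$causal_pos > genome$chromosomes[[cross$causal_chrom]]) {
    stop("`causal_pos` exceeds the length of chromosome ", cross$causal_chrom,
         call. = FALSE)
  }
  pieces <- lapply(names(genome$chromosomes), function(ch) {
    len <- genome$chromosomes[[ch]]
    if (!is.null(cross$site_positions)) {
      pos <- sort(unique(cross$site_positions[[ch]]))
      if (length(pos) && (min(pos) < 1 || max(pos) > len)) {
        stop("explicit site positions fall outside chromosome ", ch,
             call. = FALSE)
      }
    } else {
      n <- min(cross$sites_per_chrom, len)
      pos <- sort(sample.int(len, n))
    }
    pos <- as.numeric(pos)
    causal <- rep(FALSE, length(pos))
    if (ch == cross$causal_chrom) {
      if (!cross$causal_pos %in% pos) {
        pos <- sort(c(pos, cross$causal_pos))
        causal <- rep(FALSE, length(pos))
      }
      causal[pos == cross$causal_pos] <- TRUE
    }
    data.frame(chrom = rep(ch, length(pos)), pos = pos, causal = causal,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, pieces)
  sites$cm <- sites$pos / 1e6 * genome$cm_per_mb
  sites
}

# Parental-origin matrix for n_gametes recombinant gametes at the given
# genetic positions (cM) on one chromosome. Crossovers are Poisson with mean
# equal to the chromosome's genetic length in Morgans and land uniformly on
# the genetic map (Haldane model, no interference). Origin coding: 1 =
# restorer parent, 0 = CMS parent.
sim_gametes_chrom <- function(n_gametes, site_cm, chrom_cm) {
  m <- length(site_cm)
  start <- sample(0:1, n_gametes, replace = TRUE)
  origin <- matrix(start, nrow = n_gametes, ncol = m)
  n_xo <- stats::rpois(n_gametes, chrom_cm / 100)
  for (g in which(n_xo > 0L)) {
    xo <- sort(stats::runif(n_xo[g], 0, chrom_cm))
    origin[g, ] <- bitwXor(start[g], findInterval(site_cm, xo) %% 2L)
  }
  origin
}

#' Simulate an F2 population segregating a dominant restorer allele
#'
#' Each F2 plant is the union of two independent gametes; each gamete is a
#' recombinant mosaic of the two parental haplotypes with per-chromosome
#' crossover counts drawn from a Poisson with mean equal to the chromosome's
#' genetic length in Morgans (Haldane, no interference). Genotypes count
#' restorer-parent alleles (0, 1 or 2); a plant is fertile iff its genotype
#' at the causal site is at least 1 (dominant single-gene model).
#'
#' @param genome A [genome_map()].
#' @param cross A [cross_config()].
#' @return An object of class `f2_population`: a list with
#'   \describe{
#'     \item{sites}{data frame of site `chrom`, `pos`, `cm`, `causal`.}
#'     \item{gam1,gam2}{integer matrices (`n_f2` x sites) of parental origin
#'       per gamete (1 = restorer parent).}
#'     \item{genotypes}{`gam1 + gam2`, restorer-allele counts.}
#'     \item{fertile}{logical phenotype vector.}
#'   }
#' @seealso [make_bulks()], [simulate_pool_reads()]
#' @export
simulate_f2_population <- function(genome, cross = cross_config()) {
  stopifnot(inherits(genome, "genome_map"), inherits(cross, "cross_config"))
  sites <- place_sites(genome, cross)
  if (nrow(sites) == 0L) stop("no variant sites to simulate", call. = FALSE)
  n <- cross$n_f2
  gam1 <- gam2 <- matrix(0L, nrow = n, ncol = nrow(sites))
  for (ch in names(genome$chromosomes)) {
    j <- which(sites$chrom == ch)
    if (length(j) == 0L) next
    chrom_cm <- genome$chromosomes[[ch]] / 1e6 * genome$cm_per_mb
    gam1[, j] <- sim_gametes_chrom(n, sites$cm[j], chrom_cm)
    gam2[, j] <- sim_gametes_chrom(n, sites$cm[j], chrom_cm)
  }
  geno <- gam1 + gam2
  causal_idx <- which(sites$causal)
  fertile <- geno[, causal_idx] >= 1L
  structure(list(sites = sites, gam1 = gam1, gam2 = gam2,
                 genotypes = geno, fertile = fertile, cross = cross),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat("<f2_population> ", nrow(x$genotypes), " plants, ", nrow(x$sites),
      " sites (", sum(x$fertile), " fertile / ", sum(!x$fertile),
      " sterile)\n", sep = "")
  invisible(x)
}

#' Select extreme-phenotype bulks from an F2 population
#'
#' Bulks are disjoint random subsets of the fertile and sterile phenotype
#' classes, of exactly the configured sizes.
#'
#' @param pop An [simulate_f2_population()] result.
#' @param n_fertile,n_sterile Bulk sizes; default to the population's cross
#'   configuration.
#' @return An object of class `bsa_bulks`: a list with integer index vectors
#'   `fertile` and `sterile` into the population.
#' @export
make_bulks <- function(pop, n_fertile = pop$cross$n_fertile_bulk,
                       n_sterile = pop$cross$n_sterile_bulk) {
  stopifnot(inherits(pop, "f2_population"))
  fert <- which(pop$fertile)
  ster <- which(!pop$fertile)
  if (length(fert) < n_fertile) {
    stop("only ", length(fert), " fertile plants available for a bulk of ",
         n_fertile, "; increase `n_f2`", call. = FALSE)
  }
  if (length(ster) < n_sterile) {
    stop("only ", length(ster), " sterile plants available for a bulk of ",
         n_sterile, "; increase `n_f2`", call. = FALSE)
  }
  structure(list(fertile = sort(sample(fert, n_fertile)),
                 sterile = sort(sample(ster, n_sterile))),
            class = "bsa_bulks")
}

#' Restorer-allele frequency of a bulk at every site
#'
#' @param pop An `f2_population`.
#' @param plants Integer indices of the bulked plants.
#' @return Numeric vector of restorer-parent allele frequencies, one per site.
#' @export
bulk_allele_freq <- function(pop, plants) {
  stopifnot(inherits(pop, "f2_population"), length(plants) >= 1L)
  colSums(pop$genotypes[plants, , drop = FALSE]) / (2 * length(plants))
}

# random allele pair for a site; InDels get a length-changing allele
draw_alleles <- function(n, prop_indel) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  is_indel <- stats::runif(n) < prop_indel
  ins <- stats::runif(n) < 0.5
  alt[is_indel & ins] <- paste0(ref[is_indel & ins], alt[is_indel & ins])
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins],
                                 sample(bases, sum(is_indel & !ins), replace = TRUE))
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1L, 1L)
  data.frame(ref_allele = unname(ref), alt_allele = unname(alt),
             variant_class = ifelse(is_indel, "InDel", "SNP"),
             stringsAsFactors = FALSE)
}

#' Sample pooled read depths for both bulks
#'
#' At each site the pool's frequency of the restorer-parent allele is taken
#' from the bulked genotypes; read depth is Poisson and the non-reference
#' read count binomial with a symmetric per-read error. "Non-reference"
#' (ALT) means the allele differing from the parent designated as reference
#' by `seq$ref_parent`.
#'
#' @param pop An `f2_population`.
#' @param bulks A [make_bulks()] result.
#' @param seq A [seq_config()].
#' @return A `bsa_sites` data frame (one row per locus) with columns `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `variant_class`, `f_ref`, `f_alt`,
#'   `s_ref`, `s_alt`, plus a `truth` attribute (data frame with the bulk
#'   restorer-allele frequencies and the causal flag).
#' @export
simulate_pool_reads <- function(pop, bulks, seq = seq_config()) {
  stopifnot(inherits(pop, "f2_population"), inherits(bulks, "bsa_bulks"),
            inherits(seq, "seq_config"))
  n_sites <- nrow(pop$sites)
  f_freq <- bulk_allele_freq(pop, bulks$fertile)
  s_freq <- bulk_allele_freq(pop, bulks$sterile)
  ref_is_restorer <- switch(seq$ref_parent,
    sterile  = rep(FALSE, n_sites),
    restorer = rep(TRUE, n_sites),
    random   = stats::runif(n_sites) < 0.5)
  # pool frequency of the ALT (non-reference) allele
  f_alt_freq <- ifelse(ref_is_restorer, 1 - f_freq, f_freq)
  s_alt_freq <- ifelse(ref_is_restorer, 1 - s_freq, s_freq)
  eps <- seq$error_rate
  sample_pool <- function(alt_freq, mean_depth) {
    depth <- stats::rpois(n_sites, mean_depth)
    p <- alt_freq * (1 - eps) + (1 - alt_freq) * eps
    alt <- stats::rbinom(n_sites, depth, p)
    list(ref = depth - alt, alt = alt)
  }
  fp <- sample_pool(f_alt_freq, seq$mean_depth[1])
  sp <- sample_pool(s_alt_freq, seq$mean_depth[2])
  alleles <- draw_alleles(n_sites, pop$cross$prop_indel)
  sites <- data.frame(chrom = pop$sites$chrom, pos = pop$sites$pos,
                      alleles,
                      f_ref = fp$ref, f_alt = fp$alt,
                      s_ref = sp$ref, s_alt = sp$alt,
                      stringsAsFactors = FALSE)
  class(sites) <- c("bsa_sites", "data.frame")
  attr(sites, "truth") <- data.frame(
    chrom = pop$sites$chrom, pos = pop$sites$pos,
    f_freq = f_freq, s_freq = s_freq, causal = pop$sites$causal,
    stringsAsFactors = FALSE)
  sites
}

#' Simulate a complete bulked-segregant sequencing experiment
#'
#' Convenience wrapper: population, bulks, then pooled reads, under one seed.
#'
#' @inheritParams simulate_f2_population
#' @inheritParams simulate_pool_reads
#' @param seq A [seq_config()].
#' @param seed Optional integer seed applied before any draw.
#' @return A list with elements `pop`, `bulks` and `sites` (a `bsa_sites`
#'   data frame carrying the `truth` attribute).
#' @examples
#' ex <- simulate_bsa_experiment(
#'   genome_map(c(chr1 = 5e6), cm_per_mb = 2),
#'   cross_config(n_f2 = 200, causal_chrom = "chr1", causal_pos = 2.5e6,
#'                sites_per_chrom = 50),
#'   seq_config(mean_depth = 60), seed = 1)
#' head(ex$sites)
#' @export
simulate_bsa_experiment <- function(genome = genome_map(),
                                    cross = cross_config(),
                                    seq = seq_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- simulate_f2_population(genome, cross)
  bulks <- make_bulks(pop)
  sites <- simulate_pool_reads(pop, bulks, seq)
  list(pop = pop, bulks = bulks, sites = sites)
}
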