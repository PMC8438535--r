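# Segregation-ratio testing and recombinant-count linkage distances.

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Tests observed fertile/sterile counts against an expected Mendelian
#' ratio (default 3:1, the F2 expectation for a single dominant locus).
#' Yates' continuity correction is applied by default — the convention for
#' one-degree-of-freedom segregation tests — with the corrected deviation
#' `|O - E| - 0.5` floored at zero so a perfect fit yields a statistic of
#' exactly 0.
#'
#' @param n_fertile,n_sterile Observed class counts.
#' @param ratio Expected ratio as a length-2 numeric vector (default
#'   `c(3, 1)`).
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return An object of class `segregation_test`: a list with `observed`,
#'   `expected`, `chi2`, `df` (1), `p_value` and `correction`.
#' @examples
#' segregation_chi_square(1606, 555)  # chi2 = 0.5012
#' @export
segregation_chi_square <- function(n_fertile, n_sterile, ratio = c(3, 1),
                                   yates = TRUE) {
  if (any(c(n_fertile, n_sterile) < 0) || n_fertile + n_sterile <= 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  if (length(ratio) != 2L || any(ratio <= 0)) {
    stop("`ratio` must be two positive numbers", call. = FALSE)
  }
  obs <- c(fertile = n_fertile, sterile = n_sterile)
  expected <- sum(obs) * ratio / sum(ratio)
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  structure(list(observed = obs,
                 expected = stats::setNames(expected, names(obs)),
                 chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 correction = yates),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("Segregation chi-square test",
      if (x$correction) "(Yates-corrected)", "\n")
  cat(sprintf("  observed: %d fertile / %d sterile;  expected: %.2f / %.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  chi2 = %.4f, df = %d, P = %.4f\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Classify a sterile plant as recombinant at a linked marker
#'
#' A sterile F2 plant is homozygous for the non-restorer allele at the
#' causal locus; any restorer-parent allele at a linked marker therefore
#' evidences a marker-locus crossover in at least one of its gametes.
#' Genotypes are coded as the count of restorer-parent marker alleles
#' (0, 1 or 2).
#'
#' @param marker_genotype Integer vector of marker genotypes in `{0, 1, 2}`.
#' @return Logical vector: `TRUE` where the plant is recombinant.
#' @export
classify_recombinant <- function(marker_genotype) {
  if (any(!marker_genotype %in% c(0L, 1L, 2L))) {
    stop("marker genotypes must be 0, 1 or 2 (restorer-allele count)",
         call. = FALSE)
  }
  marker_genotype != 0L
}

#' Genetic distance from a recombinant-plant count
#'
#' Each scored plant contributes two gametes, and at fine-mapping distances
#' at most one crossover per gamete is assumed, so the recombination
#' fraction is `r / (2 N)` for `r` recombinant plants among `N` plants, and
#' the map distance is `100 * r / (2 N)` centimorgans.
#'
#' @param n_recombinant_plants Number of recombinant plants (`r`).
#' @param n_plants Number of plants scored (`N`).
#' @return An object of class `linkage_estimate`: a list with
#'   `n_recombinant_plants`, `n_plants`, `recombination_fraction` and
#'   `distance_cm`.
#' @examples
#' genetic_distance(4, 3899)  # 0.0513 cM, i.e. 0.05 cM at two decimals
#' @export
genetic_distance <- function(n_recombinant_plants, n_plants) {
  if (n_plants <= 0) stop("`n_plants` must be positive", call. = FALSE)
  if (n_recombinant_plants < 0) {
    stop("`n_recombinant_plants` must be non-negative", call. = FALSE)
  }
  if (n_recombinant_plants > n_plants) {
    stop("more recombinant plants than plants: this would imply more than ",
         "one recombinant gamete per plant; use gamete_distance() with ",
         "gamete-level counts instead", call. = FALSE)
  }
  frac <- n_recombinant_plants / (2 * n_plants)
  structure(list(n_recombinant_plants = n_recombinant_plants,
                 n_plants = n_plants,
                 recombination_fraction = frac,
                 distance_cm = 100 * frac),
            class = "linkage_estimate")
}

#' Genetic distance from gamete-level recombinant counts
#'
#' Entry point for data scored per gamete (accommodates double
#' recombinants, which the plant-level count cannot represent).
#'
#' @param n_recombinant_gametes Number of recombinant gametes.
#' @param n_gametes Number of gametes scored.
#' @return A `linkage_estimate` (see [genetic_distance()]).
#' @export
gamete_distance <- function(n_recombinant_gametes, n_gametes) {
  if (n_gametes <= 0) stop("`n_gametes` must be positive", call. = FALSE)
  if (n_recombinant_gametes < 0 || n_recombinant_gametes > n_gametes) {
    stop("`n_recombinant_gametes` must lie in [0, n_gametes]", call. = FALSE)
  }
  frac <- n_recombinant_gametes / n_gametes
  structure(list(n_recombinant_plants = NA_integer_,
                 n_plants = NA_integer_,
                 n_recombinant_gametes = n_recombinant_gametes,
                 n_gametes = n_gametes,
                 recombination_fraction = frac,
                 distance_cm = 100 * frac),
            class = "linkage_estimate")
}

#' @export
print.linkage_estimate <- function(x, ...) {
  if (!is.na(x$n_plants)) {
    cat(sprintf("Linkage estimate: %d recombinant plant(s) / %d plants\n",
                x$n_recombinant_plants, x$n_plants))
  } else {
    cat(sprintf("Linkage estimate: %d recombinant gamete(s) / %d gametes\n",
                x$n_recombinant_gametes, x$n_gametes))
  }
  cat(sprintf("  recombination fraction = %.4f;  distance = %.2f cM\n",
              x$recombination_fraction, x$distance_cm))
  invisible(x)
}

#' Estimate marker-locus distance from simulated sterile plants
#'
#' Applies [classify_recombinant()] to the sterile plants of a simulated F2
#' population at a chosen marker site, then [genetic_distance()]; the true
#' Haldane map distance between marker and causal locus is attached for
#' recovery testing. An unlinked marker (different chromosome) is accepted
#' with a warning: its recombination fraction drifts to the independent
#' assortment limit of 0.5 and the cM value is meaningless.
#'
#' @param pop An [simulate_f2_population()] result.
#' @param marker_site Row index of the marker in `pop$sites` (or a site
#'   matched by `chrom` and `pos` when given as a list).
#' @return A `linkage_estimate` with extra fields `true_distance_cm` (`NA`
#'   when unlinked) and `n_sterile`.
#' @export
estimate_distance_from_simulation <- function(pop, marker_site) {
  stopifnot(inherits(pop, "f2_population"))
  if (is.list(marker_site) && !is.null(marker_site$chrom)) {
    marker_site <- which(pop$sites$chrom == marker_site$chrom &
                           pop$sites$pos == marker_site$pos)
  }
  if (length(marker_site) != 1L || is.na(marker_site) ||
      marker_site < 1L || marker_site > nrow(pop$sites)) {
    stop("`marker_site` does not identify a single simulated site", call. = FALSE)
  }
  causal_idx <- which(pop$sites$causal)
  sterile <- which(!pop$fertile)
  if (length(sterile) == 0L) stop("no sterile plants in the population", call. = FALSE)
  geno <- pop$genotypes[sterile, marker_site]
  rec <- classify_recombinant(geno)
  est <- genetic_distance(sum(rec), length(sterile))
  same_chrom <- pop$sites$chrom[marker_site] == pop$sites$chrom[causal_idx]
  if (!same_chrom) {
    warning("marker and causal locus are on different chromosomes; ",
            "the recombination fraction should approach 0.5 and the ",
            "distance is not meaningful")
    est$true_distance_cm <- NA_real_
  } else {
    est$true_distance_cm <- abs(pop$sites$cm[marker_site] -
                                  pop$sites$cm[causal_idx])
  }
  est$n_sterile <- length(sterile)
  est
}
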