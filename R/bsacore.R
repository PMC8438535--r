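# The scan statistic: per-site indices, the 0.3 quality filter, sliding
# windows, delta index, and candidate-interval calling.

#' Per-site SNP/InDel index
#'
#' The proportion of a pool's reads at one site that differ from the
#' reference genome: `alt / (ref + alt)`. Undefined (NA) when the pool has
#' zero depth at the site.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorised).
#' @return Numeric vector of indices in `[0, 1]`, `NA` where depth is zero.
#' @examples
#' site_index(10, 10)   # 0.5
#' site_index(35, 15)   # 0.3, the filter boundary
#' @export
site_index <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0, na.rm = TRUE) || any(alt_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  depth <- ref_reads + alt_reads
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Delta index between the sterile and fertile pools
#'
#' `s_index - f_index`: positive where the sterile pool is enriched for the
#' non-reference allele relative to the fertile pool. Lies in `[-1, 1]`.
#'
#' @param s_index,f_index Pool indices (vectorised).
#' @return Numeric vector of differences.
#' @export
delta_index <- function(s_index, f_index) {
  s_index - f_index
}

#' Add index columns to a site table
#'
#' Computes `f_index`, `s_index` and `delta = s_index - f_index` from the
#' per-pool read counts.
#'
#' @param sites A `bsa_sites` data frame (see [simulate_pool_reads()] or
#'   [read_sites()]).
#' @return The input with `f_index`, `s_index`, `delta` columns appended.
#' @export
compute_indices <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("f_ref", "f_alt", "s_ref", "s_alt") %in% names(sites)))
  sites$f_index <- site_index(sites$f_ref, sites$f_alt)
  sites$s_index <- site_index(sites$s_ref, sites$s_alt)
  sites$delta <- delta_index(sites$s_index, sites$f_index)
  if (!inherits(sites, "bsa_sites")) class(sites) <- c("bsa_sites", class(sites))
  sites
}

#' Discard low-index (low-quality) sites
#'
#' Reproduces the quality filter that deletes loci whose index falls below
#' the threshold in both pools. Under the default `"both"` policy a site is
#' discarded iff `f_index < threshold` AND `s_index < threshold`; this is
#' the convention that preserves the causal-region signal, where one pool
#' sits near 0 and the other near 1. The stricter `"either"` policy discards
#' a site when either pool falls below the threshold. Sites with an
#' undefined index in either pool are always discarded. The comparison is a
#' strict `<`, so sites exactly at the threshold are retained.
#'
#' @param sites A site table with `f_index` and `s_index` columns
#'   ([compute_indices()]).
#' @param threshold Index threshold in `[0, 1]`; default 0.3.
#' @param policy `"both"` (default) or `"either"`.
#' @return The retained subset, original order preserved. The number of
#'   discarded sites is recorded in attribute `n_discarded`.
#' @export
filter_low_index <- function(sites, threshold = 0.3,
                             policy = c("both", "either")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(sites),
            all(c("f_index", "s_index") %in% names(sites)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single value in [0, 1]", call. = FALSE)
  }
  undefined <- is.na(sites$f_index) | is.na(sites$s_index)
  low <- if (policy == "both") {
    sites$f_index < threshold & sites$s_index < threshold
  } else {
    sites$f_index < threshold | sites$s_index < threshold
  }
  keep <- !undefined & !(low %in% TRUE)
  out <- sites[keep, , drop = FALSE]
  attr(out, "truth") <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Sliding windows along one chromosome
#'
#' Full windows anchored at position 1 and advanced by `step`: starts are
#' `1, 1 + step, 1 + 2 * step, ...` with window end `start + window - 1`
#' never exceeding the chromosome length. A chromosome shorter than one
#' window yields a single window covering it entirely.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 1 Mb).
#' @param step Step (increment) in bp (default 100 kb).
#' @return Data frame with columns `start`, `end` (1-based inclusive).
#' @examples
#' nrow(make_windows(3e6))  # 21 windows
#' @export
make_windows <- function(chrom_length, window = 1e6, step = 1e5) {
  if (!is.numeric(window) || window <= 0 || !is.numeric(step) || step <= 0) {
    stop("`window` and `step` must be positive", call. = FALSE)
  }
  if (!is.numeric(chrom_length) || length(chrom_length) != 1L || chrom_length <= 0) {
    stop("`chrom_length` must be a single positive number", call. = FALSE)
  }
  if (chrom_length < window) {
    return(data.frame(start = 1, end = chrom_length))
  }
  starts <- seq(1, chrom_length - window + 1, by = step)
  data.frame(start = starts, end = starts + window - 1)
}

#' Sliding-window scan of pool indices
#'
#' For every window on every chromosome of the genome map, averages the
#' per-site pool indices and per-site delta over the sites falling inside
#' the window (window start <= pos <= window end). Windows with no sites
#' carry `NA` means and are excluded from interval calling downstream.
#'
#' @param sites An indexed, filtered site table sorted by (chrom, pos).
#' @param genome A [genome_map()] (or named vector of chromosome lengths).
#' @param window,step Window size and step in bp (defaults 1 Mb / 100 kb).
#' @param track `"both"` (default), `"snp"` or `"indel"`: which variant
#'   class to scan.
#' @return A `scan_windows` data frame: `chrom`, `start`, `end`, `n_sites`,
#'   `n_snp_sites`, `n_indel_sites`, `mean_f_index`, `mean_s_index`,
#'   `mean_delta`. Window and step sizes are kept as attributes.
#' @export
window_scan <- function(sites, genome, window = 1e6, step = 1e5,
                        track = c("both", "snp", "indel")) {
  track <- match.arg(track)
  if (inherits(genome, "genome_map")) genome <- genome$chromosomes
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "f_index", "s_index", "delta") %in% names(sites)))
  bad <- setdiff(unique(sites$chrom), names(genome))
  if (length(bad)) {
    stop("site chromosome(s) absent from the genome map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(sites$f_index) || anyNA(sites$s_index)) {
    warning("sites with undefined indices are ignored in the scan")
    sites <- sites[!is.na(sites$f_index) & !is.na(sites$s_index), , drop = FALSE]
  }
  if (track != "both" && "variant_class" %in% names(sites)) {
    sites <- sites[tolower(sites$variant_class) ==
                     ifelse(track == "snp", "snp", "indel"), , drop = FALSE]
  }
  out <- lapply(names(genome), function(ch) {
    w <- make_windows(genome[[ch]], window, step)
    cs <- sites[sites$chrom == ch, , drop = FALSE]
    cs <- cs[order(cs$pos), , drop = FALSE]
    pos <- cs$pos
    is_snp <- if ("variant_class" %in% names(cs)) {
      tolower(cs$variant_class) == "snp"
    } else rep(NA, nrow(cs))
    # prefix sums give O(1) window means over the sorted sites
    cf <- c(0, cumsum(cs$f_index)); css <- c(0, cumsum(cs$s_index))
    cd <- c(0, cumsum(cs$delta));   csn <- c(0, cumsum(is_snp %in% TRUE))
    i1 <- findInterval(w$start - 0.5, pos) + 1L
    i2 <- findInterval(w$end + 0.5, pos)
    n <- pmax(i2 - i1 + 1L, 0L)
    sum_rng <- function(cum) ifelse(n > 0, cum[i2 + 1L] - cum[i1], NA_real_)
    n_snp <- ifelse(n > 0, csn[i2 + 1L] - csn[i1], 0)
    data.frame(chrom = ch, start = w$start, end = w$end,
               n_sites = n, n_snp_sites = as.integer(n_snp),
               n_indel_sites = as.integer(n - n_snp),
               mean_f_index = sum_rng(cf) / n,
               mean_s_index = sum_rng(css) / n,
               mean_delta = sum_rng(cd) / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("scan_windows", "data.frame")
  attr(res, "window") <- window
  attr(res, "step") <- step
  attr(res, "track") <- track
  res
}

#' Call candidate intervals from a window scan
#'
#' Merges runs of consecutive informative windows whose `|mean_delta|`
#' reaches the detection threshold. Two qualifying windows are consecutive
#' when their starts differ by exactly one step (or by up to
#' `max_gap + 1` steps when a gap tolerance is allowed). An interval spans
#' from the first qualifying window's start to the last one's end, and
#' records the peak `|mean_delta|` and the number of windows merged.
#'
#' @param windows A [window_scan()] result.
#' @param threshold Detection threshold on `|mean_delta|` (default 0.5, the
#'   guide line used for a locus fully linked in one bulk).
#' @param min_windows Minimum run length to report (default 1).
#' @param step Window step in bp; taken from the scan attributes when
#'   available.
#' @param max_gap Number of non-qualifying steps tolerated inside a run
#'   (default 0).
#' @return A `candidate_intervals` data frame: `chrom`, `start`, `end`,
#'   `width` (bp, `end - start + 1`), `peak_abs_delta`, `n_windows`.
#' @export
call_intervals <- function(windows, threshold = 0.5, min_windows = 1,
                           step = attr(windows, "step"), max_gap = 0) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end", "mean_delta") %in% names(windows)))
  if (is.null(step)) step <- 1e5
  qual <- windows[!is.na(windows$mean_delta) &
                    abs(windows$mean_delta) >= threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      width = numeric(), peak_abs_delta = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (nrow(qual) == 0L) {
    class(empty) <- c("candidate_intervals", "data.frame")
    return(empty)
  }
  qual <- qual[order(qual$chrom, qual$start), , drop = FALSE]
  new_run <- c(TRUE, qual$chrom[-1] != qual$chrom[-nrow(qual)] |
                 diff(qual$start) > (max_gap + 1) * step)
  run <- cumsum(new_run)
  pieces <- lapply(split(qual, run), function(q) {
    data.frame(chrom = q$chrom[1], start = min(q$start), end = max(q$end),
               width = max(q$end) - min(q$start) + 1,
               peak_abs_delta = max(abs(q$mean_delta)),
               n_windows = nrow(q), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, pieces)
  res <- res[res$n_windows >= min_windows, , drop = FALSE]
  res <- merge_overlapping(res)
  rownames(res) <- NULL
  class(res) <- c("candidate_intervals", "data.frame")
  res
}

# Windows are wider than the step, so runs split by a sub-threshold window
# can still overlap physically; overlapping qualifying regions always merge.
merge_overlapping <- function(iv) {
  if (nrow(iv) < 2L) return(iv)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    j <- nrow(out)
    if (iv$chrom[i] == out$chrom[j] && iv$start[i] <= out$end[j] + 1) {
      out$end[j] <- max(out$end[j], iv$end[i])
      out$width[j] <- out$end[j] - out$start[j] + 1
      out$peak_abs_delta[j] <- max(out$peak_abs_delta[j], iv$peak_abs_delta[i])
      out$n_windows[j] <- out$n_windows[j] + iv$n_windows[i]
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Run the full scan on a site table
#'
#' Index computation, quality filtering, sliding-window averaging and
#' interval calling in one call.
#'
#' @inheritParams window_scan
#' @param index_min Low-index filter threshold (default 0.3).
#' @param delta_min Interval-calling threshold on `|mean_delta|` (default 0.5).
#' @param filter_policy Passed to [filter_low_index()].
#' @param min_windows,max_gap Passed to [call_intervals()].
#' @return List with `sites` (filtered, indexed), `windows`, `intervals`,
#'   and `n_discarded` (sites removed by the quality filter).
#' @export
bsa_scan <- function(sites, genome, window = 1e6, step = 1e5,
                     index_min = 0.3, delta_min = 0.5,
                     track = c("both", "snp", "indel"),
                     filter_policy = c("both", "either"),
                     min_windows = 1, max_gap = 0) {
  track <- match.arg(track)
  filter_policy <- match.arg(filter_policy)
  if (!all(c("f_index", "s_index", "delta") %in% names(sites))) {
    sites <- compute_indices(sites)
  }
  kept <- filter_low_index(sites, index_min, filter_policy)
  windows <- window_scan(kept, genome, window, step, track)
  intervals <- call_intervals(windows, delta_min, min_windows,
                              step = step, max_gap = max_gap)
  list(sites = kept, windows = windows, intervals = intervals,
       n_discarded = attr(kept, "n_discarded"))
}
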