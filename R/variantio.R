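# Reading and writing the formats the pipeline touches: two-sample VCF with
# allele depths in, windows TSV / intervals BED / interval report out.
# Internal coordinates are 1-based inclusive (VCF native); conversion to
# 0-based half-open happens only at the BED boundary.

F_SAMPLE <- "F_pool"
S_SAMPLE <- "S_pool"

output_header <- function(seed = NULL, params_hash = NULL) {
  paste0("# bsascan ",
         as.character(utils::packageVersion("bsascan")),
         if (!is.null(seed)) paste0(" | seed=", seed),
         if (!is.null(params_hash)) paste0(" | params=", params_hash))
}

#' Read a chromosome-length table
#'
#' A two-column tab-separated file (chromosome name, length in bp), no
#' header; `#` lines are ignored.
#'
#' @param path File path.
#' @param cm_per_mb Recombination-rate scalar attached to the resulting map.
#' @return A [genome_map()].
#' @export
read_genome_lengths <- function(path, cm_per_mb = 2) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_map(stats::setNames(tab$length, tab$chrom), cm_per_mb = cm_per_mb)
}

#' Write a chromosome-length table
#'
#' @param genome A [genome_map()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_genome_lengths <- function(genome, path) {
  stopifnot(inherits(genome, "genome_map"))
  utils::write.table(
    data.frame(chrom = names(genome$chromosomes),
               length = format(genome$chromosomes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# naive diploid genotype string from a pool's allele depths (pools are not
# true diploids; the GT field is informational only, AD carries the data)
gt_from_depths <- function(ref, alt) {
  ifelse(ref + alt == 0, "./.",
         ifelse(alt == 0, "0/0", ifelse(ref == 0, "1/1", "0/1")))
}

#' Write a site table as a two-sample VCF
#'
#' Emits plain-text VCF v4.2 with samples `F_pool` and `S_pool`, each
#' carrying `GT` and `AD` (reference depth, alternative depth).
#'
#' @param sites A `bsa_sites` data frame.
#' @param path Destination path (`.vcf`).
#' @param genome Optional [genome_map()] used for `##contig` header lines.
#' @param seed Optional seed recorded in the header.
#' @param params_hash Optional parameter hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, genome = NULL, seed = NULL,
                      params_hash = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref_allele", "alt_allele",
                  "f_ref", "f_alt", "s_ref", "s_alt") %in% names(sites)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", sub("^# ", "", output_header(seed, params_hash))),
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%s>", names(genome$chromosomes),
              format(genome$chromosomes, scientific = FALSE, trim = TRUE))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", F_SAMPLE, S_SAMPLE, sep = "\t"))
  body <- paste(sites$chrom,
                format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref_allele, sites$alt_allele, ".", "PASS", ".",
                "GT:AD",
                paste0(gt_from_depths(sites$f_ref, sites$f_alt), ":",
                       sites$f_ref, ",", sites$f_alt),
                paste0(gt_from_depths(sites$s_ref, sites$s_alt), ":",
                       sites$s_ref, ",", sites$s_alt),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled variant sites from a VCF
#'
#' Expects a VCF with the two pool samples carrying an `AD` field
#' (reference depth, alternative depth). Multiallelic records (more than
#' one ALT allele) and records with a missing `AD` in either sample are
#' dropped under the default policy, with a reported count. The variant
#' class is derived from the allele lengths: equal lengths are SNPs,
#' unequal lengths InDels.
#'
#' @param path VCF file path (plain text or bgzip, as supported by vcfR).
#' @param f_sample,s_sample Sample names of the fertile and sterile pools.
#' @return A `bsa_sites` data frame; the number of dropped multiallelic
#'   records is in attribute `n_multiallelic_dropped`.
#' @export
read_sites <- function(path, f_sample = F_SAMPLE, s_sample = S_SAMPLE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  smp <- colnames(vcf@gt)[-1]
  missing <- setdiff(c(f_sample, s_sample), smp)
  if (length(missing)) {
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "),
         "; found: ", paste(smp, collapse = ", "), call. = FALSE)
  }
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    warning("VCF contains no variant records")
    out <- data.frame(chrom = character(), pos = numeric(),
                      ref_allele = character(), alt_allele = character(),
                      variant_class = character(),
                      f_ref = integer(), f_alt = integer(),
                      s_ref = integer(), s_alt = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("bsa_sites", "data.frame")
    attr(out, "n_multiallelic_dropped") <- 0L
    return(out)
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) dropped")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x, which_rec) {
    if (anyNA(x)) {
      stop("missing AD field at record(s): ",
           paste(utils::head(paste0(fix[is.na(x), "CHROM"], ":",
                                    fix[is.na(x), "POS"]), 5L),
                 collapse = ", "), call. = FALSE)
    }
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, character(1), 1L)),
         alt = as.integer(vapply(parts, function(p) {
           if (length(p) >= 2L) p[2L] else "0"
         }, character(1))))
  }
  fad <- parse_ad(ad[, f_sample])
  sad <- parse_ad(ad[, s_sample])
  keep <- !multi
  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  out <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.numeric(fix[keep, "POS"]),
    ref_allele = ref, alt_allele = alt,
    variant_class = ifelse(nchar(ref) == nchar(alt), "SNP", "InDel"),
    f_ref = fad$ref[keep], f_alt = fad$alt[keep],
    s_ref = sad$ref[keep], s_alt = sad$alt[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bsa_sites", "data.frame")
  attr(out, "n_multiallelic_dropped") <- sum(multi)
  out
}

#' Write the truth sidecar of a simulated experiment
#'
#' Tab-separated table of the simulated bulk allele frequencies
#' (restorer-parent allele) and the causal flag, one row per site.
#'
#' @param truth The `truth` attribute of a [simulate_pool_reads()] table.
#' @param path Destination path.
#' @param seed,params_hash Recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NULL, params_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, params_hash), con)
  truth$f_freq <- sprintf("%.6f", truth$f_freq)
  truth$s_freq <- sprintf("%.6f", truth$s_freq)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format candidate intervals as a human-readable report
#'
#' One line per interval, boundaries and width in Mb with two decimals,
#' e.g. `"A09: 27.62-33.87 Mb (6.25 Mb), peak |delta| = 0.67 over 54
#' window(s)"`. States that no interval was found when the table is empty.
#'
#' @param intervals A [call_intervals()] result.
#' @return Character vector of report lines.
#' @export
format_interval_report <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) {
    return("No candidate interval reached the detection threshold.")
  }
  sprintf("%s: %.2f-%.2f Mb (%.2f Mb), peak |delta| = %.2f over %d window(s)",
          intervals$chrom, intervals$start / 1e6, intervals$end / 1e6,
          intervals$width / 1e6, intervals$peak_abs_delta,
          intervals$n_windows)
}

#' Write scan results: windows TSV, intervals BED and interval report
#'
#' The windows table is tab-separated with all means serialised to 6
#' decimals; the intervals file is BED (0-based half-open, start = 1-based
#' start - 1); the report is the [format_interval_report()] text. All three
#' begin with a `#` comment header carrying tool version, seed and
#' parameter hash.
#'
#' @param windows A [window_scan()] result.
#' @param intervals A [call_intervals()] result.
#' @param out_prefix Path prefix; writes `<prefix>_windows.tsv`,
#'   `<prefix>_intervals.bed`, `<prefix>_intervals.txt`.
#' @param seed,params_hash Recorded in the headers.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_scan_results <- function(windows, intervals, out_prefix,
                               seed = NULL, params_hash = NULL) {
  hdr <- output_header(seed, params_hash)
  paths <- c(windows = paste0(out_prefix, "_windows.tsv"),
             bed = paste0(out_prefix, "_intervals.bed"),
             report = paste0(out_prefix, "_intervals.txt"))
  w <- as.data.frame(windows)
  for (col in c("mean_f_index", "mean_s_index", "mean_delta")) {
    w[[col]] <- ifelse(is.na(w[[col]]), "NA", sprintf("%.6f", w[[col]]))
  }
  w$start <- format(w$start, scientific = FALSE, trim = TRUE)
  w$end <- format(w$end, scientific = FALSE, trim = TRUE)
  con <- file(paths[["windows"]], "w")
  writeLines(hdr, con)
  utils::write.table(w, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  bed_lines <- if (nrow(intervals)) {
    paste(intervals$chrom,
          format(intervals$start - 1, scientific = FALSE, trim = TRUE),
          format(intervals$end, scientific = FALSE, trim = TRUE),
          sprintf("interval_%d", seq_len(nrow(intervals))),
          sprintf("%.6f", intervals$peak_abs_delta),
          sep = "\t")
  } else character()
  writeLines(c(hdr, bed_lines), paths[["bed"]])
  writeLines(c(hdr, format_interval_report(intervals)), paths[["report"]])
  invisible(paths)
}

#' Read a windows TSV back into a scan table
#'
#' Inverse of the windows file written by [write_scan_results()].
#'
#' @param path File path.
#' @return A `scan_windows` data frame.
#' @export
read_scan_windows <- function(path) {
  w <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  for (col in c("mean_f_index", "mean_s_index", "mean_delta")) {
    w[[col]] <- suppressWarnings(as.numeric(w[[col]]))
  }
  class(w) <- c("scan_windows", "data.frame")
  w
}
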