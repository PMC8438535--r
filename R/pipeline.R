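# Orchestration: one reproducible simulate -> scan -> report run, plus the
# committed-size fixtures the test suite uses.

#' Assemble a run configuration
#'
#' Collects the genome, cross, sequencing and scan settings of one pipeline
#' run. Equivalent to reading a YAML configuration with the same sections.
#'
#' @param genome A [genome_map()].
#' @param cross A [cross_config()].
#' @param sequencing A [seq_config()].
#' @param scan Named list of scan settings; recognised entries `window`,
#'   `step`, `index_min`, `delta_min`, `track`, `filter_policy`,
#'   `min_windows`, `max_gap` (missing entries take the scan defaults).
#' @param seed Integer seed for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genome = genome_map(), cross = cross_config(),
                       sequencing = seq_config(), scan = list(), seed = 1L) {
  stopifnot(inherits(genome, "genome_map"), inherits(cross, "cross_config"),
            inherits(sequencing, "seq_config"), is.list(scan))
  defaults <- list(window = 1e6, step = 1e5, index_min = 0.3, delta_min = 0.5,
                   track = "both", filter_policy = "both", min_windows = 1,
                   max_gap = 0)
  unknown <- setdiff(names(scan), names(defaults))
  if (length(unknown)) {
    stop("unknown scan setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  scan <- utils::modifyList(defaults, scan)
  structure(list(genome = genome, cross = cross, sequencing = sequencing,
                 scan = scan, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Sections `genome` (`chromosomes` as a name: length mapping,
#' `cm_per_mb`), `cross`, `sequencing` and `scan` mirror the arguments of
#' [genome_map()], [cross_config()], [seq_config()] and [run_config()];
#' unknown keys raise an error naming the offending path.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(section, builder, transform = identity) {
    if (is.null(raw[[section]])) return(builder())
    args <- transform(raw[[section]])
    known <- names(formals(builder))
    unknown <- setdiff(names(args), known)
    if (length(unknown)) {
      stop("unknown key(s) in config section '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    do.call(builder, args)
  }
  genome <- take("genome", genome_map, function(g) {
    if (!is.null(g$chromosomes)) g$chromosomes <- unlist(g$chromosomes)
    g
  })
  cfg <- run_config(
    genome = genome,
    cross = take("cross", cross_config),
    sequencing = take("sequencing", seq_config),
    scan = if (is.null(raw$scan)) list() else raw$scan,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(
    genome = list(chromosomes = as.list(config$genome$chromosomes),
                  cm_per_mb = config$genome$cm_per_mb),
    cross = unclass(config$cross),
    sequencing = unclass(config$sequencing),
    scan = config$scan,
    seed = config$seed), path)
  invisible(path)
}

#' Parameter hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; equal configurations always
#' yield equal hashes, which every output header records.
#'
#' @param config A `run_config`.
#' @return A 32-character hex string.
#' @export
params_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  paste0(...)))
}

#' Run the full pipeline: simulate, scan, report
#'
#' With no input VCF the configured experiment is simulated and written out
#' (VCF plus truth sidecar); with `vcf` given, simulation is skipped and
#' the sites are read from the file (scan-only mode). Either way the sites
#' are indexed, quality-filtered, scanned in sliding windows, and candidate
#' intervals are called; a segregation test on the simulated population
#' and a JSON run manifest complete the outputs. On error, partial outputs
#' of the failed run are removed.
#'
#' @param config A [run_config()].
#' @param out_prefix Path prefix for all outputs.
#' @param vcf Optional path to an existing two-sample VCF; enables
#'   scan-only mode.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with `sites`, `windows`, `intervals`,
#'   `segregation` (NULL in scan-only mode), `manifest` and `paths`.
#' @export
run_pipeline <- function(config, out_prefix, vcf = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- if (quiet) function(...) invisible() else log_msg
  hash <- params_hash(config)
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  segregation <- NULL
  t0 <- Sys.time()
  tryCatch({
    set.seed(config$seed)
    if (is.null(vcf)) {
      say("INFO", "simulate: ", config$cross$n_f2, " F2 plants, ",
          length(config$genome$chromosomes), " chromosomes")
      pop <- simulate_f2_population(config$genome, config$cross)
      bulks <- make_bulks(pop)
      sites <- simulate_pool_reads(pop, bulks, config$sequencing)
      truth <- attr(sites, "truth")
      note(write_vcf(sites, paste0(out_prefix, ".vcf"), config$genome,
                     seed = config$seed, params_hash = hash))
      note(write_truth(truth, paste0(out_prefix, "_truth.tsv"),
                       seed = config$seed, params_hash = hash))
      segregation <- segregation_chi_square(sum(pop$fertile),
                                            sum(!pop$fertile))
      n_input <- nrow(sites)
      n_multi <- 0L
    } else {
      say("INFO", "scan-only mode: reading ", vcf)
      sites <- read_sites(vcf)
      n_input <- nrow(sites)
      n_multi <- attr(sites, "n_multiallelic_dropped")
    }
    say("INFO", "scan: ", n_input, " sites")
    scan <- config$scan
    res <- bsa_scan(sites, config$genome,
                    window = scan$window, step = scan$step,
                    index_min = scan$index_min, delta_min = scan$delta_min,
                    track = scan$track, filter_policy = scan$filter_policy,
                    min_windows = scan$min_windows, max_gap = scan$max_gap)
    paths <- write_scan_results(res$windows, res$intervals, out_prefix,
                                seed = config$seed, params_hash = hash)
    for (p in paths) note(p)
    if (!is.null(segregation)) {
      seg_path <- note(paste0(out_prefix, "_segregation.txt"))
      con <- file(seg_path, "w")
      writeLines(output_header(config$seed, hash), con)
      sink(con); print(segregation); sink()
      close(con)
    }
    manifest <- list(
      tool = "bsascan",
      version = as.character(utils::packageVersion("bsascan")),
      seed = config$seed,
      params_hash = hash,
      parameters = yaml::yaml.load(yaml::as.yaml(list(
        genome = list(chromosomes = as.list(config$genome$chromosomes),
                      cm_per_mb = config$genome$cm_per_mb),
        cross = unclass(config$cross),
        sequencing = unclass(config$sequencing),
        scan = config$scan))),
      mode = if (is.null(vcf)) "simulate" else "scan-only",
      counts = list(
        sites_input = n_input,
        multiallelic_dropped = n_multi,
        sites_after_index_filter = nrow(res$sites),
        windows = nrow(res$windows),
        informative_windows = sum(!is.na(res$windows$mean_delta)),
        intervals = nrow(res$intervals)),
      segregation = if (!is.null(segregation)) {
        list(fertile = unname(segregation$observed[1]),
             sterile = unname(segregation$observed[2]),
             chi2 = segregation$chi2, p_value = segregation$p_value)
      })
    manifest_path <- note(paste0(out_prefix, "_manifest.json"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("INFO", sprintf("done in %.1f s; %d interval(s) called",
                        as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        nrow(res$intervals)))
    invisible(list(sites = res$sites, windows = res$windows,
                   intervals = res$intervals, segregation = segregation,
                   manifest = manifest, paths = c(written)))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Generate a committed-size test fixture
#'
#' Writes a small simulated dataset (VCF, truth sidecar, chromosome-length
#' table, YAML config) for use in tests and examples. `"tiny"` is two 2-Mb
#' chromosomes with 50 sites each; `"small"` is the default desk-scale
#' genome at reduced site density. Repeated invocation with the same seed
#' produces byte-identical files.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1L,
                         dir = tempfile("fixture")) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- switch(size,
    tiny = run_config(
      genome = genome_map(c(chr1 = 2e6, chr2 = 2e6), cm_per_mb = 2),
      cross = cross_config(n_f2 = 300, causal_chrom = "chr1",
                           causal_pos = 1e6, sites_per_chrom = 50),
      sequencing = seq_config(mean_depth = 60),
      scan = list(window = 5e5, step = 1e5),
      seed = seed),
    small = run_config(seed = seed))
  prefix <- file.path(dir, size)
  write_genome_lengths(config$genome, paste0(prefix, "_genome.tsv"))
  write_run_config(config, paste0(prefix, "_config.yaml"))
  res <- run_pipeline(config, prefix, quiet = TRUE)
  invisible(res)
}

#' Plot delta-index tracks along the genome
#'
#' One panel per chromosome: per-site delta as points, window means as a
#' line, with guide lines at the positive and negative detection
#' thresholds. Requires ggplot2.
#'
#' @param windows A [window_scan()] result.
#' @param sites Optional indexed site table for the per-site points.
#' @param delta_min Guide-line level (default 0.5).
#' @return A ggplot object.
#' @export
plot_delta <- function(windows, sites = NULL, delta_min = 0.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_delta() requires the ggplot2 package", call. = FALSE)
  }
  w <- as.data.frame(windows)
  w$mid <- (w$start + w$end) / 2
  p <- ggplot2::ggplot()
  if (!is.null(sites)) {
    p <- p + ggplot2::geom_point(
      data = as.data.frame(sites),
      ggplot2::aes(x = .data$pos / 1e6, y = .data$delta),
      colour = "grey70", size = 0.4, alpha = 0.6)
  }
  p +
    ggplot2::geom_line(data = w[!is.na(w$mean_delta), ],
                       ggplot2::aes(x = .data$mid / 1e6, y = .data$mean_delta),
                       colour = "blue") +
    ggplot2::geom_hline(yintercept = c(-delta_min, delta_min),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "Position (Mb)", y = "delta(SNP/InDel-index)") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
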