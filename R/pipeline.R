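#' Pipeline configuration
#'
#' All numeric constants of the pipeline in one serializable object:
#' motif and scoring parameters of the repeat finder, the three structure
#' criteria (200 bp terminus window, 60 bp anchor), the concatenation rule
#' (50 bp segments, 250 bp breakpoints), pangenome end length (25 kb),
#' the MAPQ tiers (>= 20 default profile, >= 10 cancer profile, > 5
#' phased-allele assignment), simulation defaults, and the CV thresholds
#' (0.8 / 0.55) of the TMM classifier.
#'
#' @param ... Named overrides of default entries, using nested lists
#'   (e.g. `filter = list(terminus_window = 150)`). Unknown keys are
#'   rejected.
#' @param profile `"default"` or `"cancer"` (lowers the assignment MAPQ
#'   threshold to 10).
#' @param seed Integer seed recorded in the config.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(..., profile = c("default", "cancer"),
                            seed = 1L) {
  profile <- match.arg(profile)
  cfg <- list(
    motif = list(canonical_motif = "TTAGGG", min_identity = 0.85,
                 min_segment_length = 50L, match = 1L, mismatch = -5L,
                 gap = -5L),
    filter = list(terminus_window = 200L, min_anchor = 60L,
                  terminal_search = 500L, chain_gap = 250L,
                  min_mean_q = 9),
    concat = list(min_segment = 50L, max_gap = 250L,
                  length_mode = "span"),
    pangenome = list(end_length = 25000L, min_overlap = 1L),
    mapq = list(arm_threshold = 20L, cancer_threshold = 10L,
                phased_min = 5L),
    sim = list(trim_range = c(0, 3000), reads_per_end = 30L,
               error_rate = 0.02,
               error_mix = c(0.5, 0.25, 0.25),
               restriction_site = "GATATC", cut_offset = 3L),
    stats = list(alt_cv = 0.8, tert_cv = 0.55, short_bp = 1000,
                 long_bp = 10000, min_reads_tmm = 100L,
                 min_arm_coverage = 20L),
    profile = profile, seed = as.integer(seed))
  overrides <- list(...)
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config section: ", key)
    if (is.list(cfg[[key]])) {
      for (sub in names(overrides[[key]])) {
        if (!sub %in% names(cfg[[key]])) {
          stop("unknown config key: ", key, "$", sub)
        }
        cfg[[key]][[sub]] <- overrides[[key]][[sub]]
      }
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  if (profile == "cancer") {
    cfg$mapq$arm_threshold <- cfg$mapq$cancer_threshold
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration
#'
#' YAML round-trip; [read_pipeline_config()] rebuilds through
#' [pipeline_config()], so unknown keys are rejected on read as well.
#'
#' @param config A `"pipeline_config"`.
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "default"
  seed <- raw$seed %||% 1L
  raw$profile <- NULL
  raw$seed <- NULL
  # cancer profile already lowered the stored threshold; restore before
  # reapplying so the constructor stays idempotent
  do.call(pipeline_config, c(raw, list(profile = profile, seed = seed)))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the YAML serialization; recorded in output headers so results
#' can be traced to the exact configuration.
#'
#' @param config A `"pipeline_config"`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full telomere-profiling pipeline
#'
#' Stage order: repeat-segment detection, structure filtering, length
#' calling, alignment (external aligner), alignment selection and arm
#' assignment, MAPQ filtering, per-sample and per-arm statistics.
#' Per-stage read counts are collected for audit.
#'
#' @param fastq Path to the reads (FASTQ, optionally gzipped), or a named
#'   character vector of sequences.
#' @param reference A `"pangenome_reference"`, or `NULL` to skip the
#'   mapping stages (bulk-only analysis).
#' @param config A [pipeline_config()].
#' @param alignments Optional pre-computed alignment table from
#'   [read_alignment_records()] (recorded-fixture mode); when `NULL` and
#'   a reference is given, minimap2 is invoked via [align_reads()].
#' @param out_dir Optional directory for TSV artifacts.
#' @return A list: `segments`, `verdicts`, `calls`, `assignments`
#'   (MAPQ-filtered), `coverage`, `bulk_summary`, `arm_summary`,
#'   `counts` (per-stage read counts), `config_hash`.
#' @export
run_pipeline <- function(fastq, reference = NULL,
                         config = pipeline_config(),
                         alignments = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    rd <- read_reads(fastq)
    reads <- rd$sequences
    mq <- rd$mean_qualities
    fastq_path <- fastq
  } else {
    reads <- fastq
    mq <- NULL
    fastq_path <- NULL
  }
  spec <- do.call(motif_spec, config$motif)
  fpar <- do.call(filter_params, config$filter)
  cpar <- do.call(concat_params, config$concat)

  counts <- list(reads_in = length(reads))
  if (length(reads) == 0L) {
    warning("no input reads; outputs are empty")
    empty <- list(segments = NULL, verdicts = NULL, calls = NULL,
                  assignments = NULL, coverage = NULL, bulk_summary = NULL,
                  arm_summary = NULL, counts = counts, config_hash = hash)
    return(empty)
  }

  segments <- find_repeat_segments_batch(reads, spec)
  counts$reads_with_segments <- length(unique(segments$read_id))

  verdicts <- apply_structure_filter_batch(reads, segments, fpar,
                                           mean_qualities = mq)
  counts$reads_passing_filter <- sum(verdicts$passed)
  fail <- verdicts$fail_reasons[!verdicts$passed]
  counts$fail_reason_counts <-
    table(unlist(strsplit(fail[nzchar(fail)], ",", fixed = TRUE)))

  read_lengths <- setNames(nchar(reads), names(reads))
  calls <- call_telomere_lengths(verdicts, segments, cpar,
                                 read_lengths = read_lengths)
  counts$length_calls <- nrow(calls)

  assignments <- NULL
  coverage <- NULL
  arm_summary <- NULL
  if (!is.null(reference)) {
    if (is.null(alignments)) {
      if (is.null(fastq_path)) {
        fastq_path <- tempfile(fileext = ".fastq")
        write_fastq(reads[calls$read_id], fastq_path)
      }
      sam <- align_reads(fastq_path, reference)
      alignments <- read_alignment_records(sam)
    }
    alignments <- alignments[alignments$read_id %in% calls$read_id, ,
                             drop = FALSE]
    assigned <- select_alignments(alignments, reference,
                                  min_overlap = config$pangenome$min_overlap)
    counts$reads_assigned <- nrow(assigned)
    assignments <- filter_by_mapq(assigned, config$mapq$arm_threshold)
    counts$reads_assigned_mapq <- nrow(assignments)
    if (nrow(assignments) > 0L) {
      coverage <- normalized_coverage(assignments)
      arm_summary <- summarize_arms(calls, assignments)
    }
  }

  bulk_summary <- if (nrow(calls) > 0L) {
    summarize_lengths(calls$telomere_length,
                      short_bp = config$stats$short_bp,
                      long_bp = config$stats$long_bp)
  } else NULL

  result <- list(segments = segments, verdicts = verdicts, calls = calls,
                 assignments = assignments, coverage = coverage,
                 bulk_summary = bulk_summary, arm_summary = arm_summary,
                 counts = counts, config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(segments, file.path(out_dir, "segments.tsv"), hash)
    write_result_tsv(verdicts, file.path(out_dir, "verdicts.tsv"), hash)
    write_result_tsv(calls, file.path(out_dir, "telomere_calls.tsv"), hash)
    if (!is.null(assignments)) {
      write_result_tsv(assignments,
                       file.path(out_dir, "assignments.tsv"), hash)
    }
    if (!is.null(coverage)) {
      write_result_tsv(coverage, file.path(out_dir, "coverage.tsv"), hash)
    }
    if (!is.null(bulk_summary)) {
      write_result_tsv(bulk_summary,
                       file.path(out_dir, "bulk_summary.tsv"), hash)
    }
    if (!is.null(arm_summary)) {
      write_result_tsv(arm_summary,
                       file.path(out_dir, "arm_summary.tsv"), hash)
    }
  }
  result
}
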