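#' Locate noisy telomeric repeat segments in a read
#'
#' Aligns the read against an unbounded tandem repetition of the telomere
#' motif (both strand forms) with a wraparound local dynamic program and
#' extracts all maximal-scoring segments. Coordinates are 0-based
#' half-open on the read as given; the read itself is never
#' reverse-complemented. Overlapping G- and C-form candidates are resolved
#' in favour of the higher-scoring one (ties toward the form expected at
#' the nearer read terminus: C-strand near the 5' end, G-strand near the
#' 3' end), after which segments shorter than `spec$min_segment_length` or
#' below `spec$min_identity` are dropped.
#'
#' @param sequence Uppercase DNA string (A/C/G/T/N). An empty string yields
#'   an empty table; any other character is an error.
#' @param spec A [motif_spec()].
#'
#' @return A data.frame with one row per emitted segment, sorted by
#'   `start`: columns `start`, `end` (0-based half-open read offsets),
#'   `form` (`"G"` or `"C"`), `identity` (fraction of matching alignment
#'   columns), `score` (integer alignment score).
#' @export
#' @examples
#' find_repeat_segments(strrep("TTAGGG", 20), motif_spec())
find_repeat_segments <- function(sequence, spec = motif_spec()) {
  stopifnot(inherits(spec, "motif_spec"), is.character(sequence),
            length(sequence) == 1L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters other than A/C/G/T/N")
  }
  if (nchar(sequence) == 0L) return(empty_segments())

  stop_score <- extraction_stop_score(spec)
  g <- dp_candidates(sequence, spec$canonical_motif, spec, stop_score)
  g$form <- rep("G", nrow(g))
  c_ <- dp_candidates(sequence, spec$complement_motif, spec, stop_score)
  c_$form <- rep("C", nrow(c_))
  cands <- rbind(g, c_)
  resolve_and_filter_segments(cands, nchar(sequence), spec)
}

#' Gap between two ordered repeat segments
#'
#' Distance in bp between the end of segment `a` and the start of segment
#' `b` on the same read; the quantity the segment-concatenation rule
#' compares against its breakpoint threshold.
#'
#' @param a,b Single-row segment records (anything with `start`/`end`),
#'   with `a` entirely before or abutting `b`.
#' @return Integer gap in bp (0 for abutting segments).
#' @export
segment_gap <- function(a, b) {
  if (a$end > b$start) stop("segments overlap: gap is undefined")
  as.integer(b$start - a$end)
}

## --- internals -------------------------------------------------------------

empty_segments <- function() {
  data.frame(start = integer(), end = integer(), form = character(),
             identity = numeric(), score = integer(),
             stringsAsFactors = FALSE)
}

# Minimum score any segment meeting both thresholds can have:
# a segment spanning >= L read bases has >= L alignment columns, of which a
# fraction >= q match, so score >= L * (q*match + (1-q)*mismatch).
extraction_stop_score <- function(spec) {
  bound <- spec$min_segment_length *
    (spec$min_identity * spec$match + (1 - spec$min_identity) * spec$mismatch)
  max(1L, as.integer(ceiling(bound)))
}

dp_candidates <- function(sequence, motif, spec, stop_score) {
  df <- .wraparound_dp_candidates(sequence, motif, spec$match, spec$mismatch,
                                  spec$gap, stop_score)
  df$identity <- ifelse(df$columns > 0, df$matches / df$columns, 0)
  df
}

# Greedy cross-form overlap resolution on the unfiltered candidate pool,
# then threshold filtering. Resolving before filtering keeps the emitted
# set monotone under a lowered identity threshold.
resolve_and_filter_segments <- function(cands, read_len, spec) {
  if (nrow(cands) == 0L) return(empty_segments())
  mid <- (cands$start + cands$end) / 2
  preferred_form <- ifelse(mid < read_len / 2, "C", "G")
  pref <- as.integer(cands$form == preferred_form)
  ord <- order(-cands$score, -pref, cands$start, cands$form)
  cands <- cands[ord, , drop = FALSE]
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ov <- keep & cands$start < cands$end[i] & cands$end > cands$start[i]
    keep[i] <- !any(ov)
  }
  out <- cands[keep, , drop = FALSE]
  out <- out[(out$end - out$start) >= spec$min_segment_length &
               out$identity >= spec$min_identity, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(start = as.integer(out$start), end = as.integer(out$end),
             form = out$form, identity = out$identity,
             score = as.integer(out$score), stringsAsFactors = FALSE)
}

#' Find repeat segments for a set of reads
#'
#' Batch form of [find_repeat_segments()] over a named [Biostrings::DNAStringSet]
#' (or named character vector), returning one long table.
#'
#' @param reads Named `DNAStringSet` or named character vector of read
#'   sequences.
#' @param spec A [motif_spec()].
#' @return A data.frame with a leading `read_id` column followed by the
#'   per-segment columns of [find_repeat_segments()].
#' @export
find_repeat_segments_batch <- function(reads, spec = motif_spec()) {
  seqs <- as.character(reads)
  ids <- names(seqs) %||% names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    seg <- find_repeat_segments(seqs[[i]], spec)
    if (nrow(seg) == 0L) return(NULL)
    cbind(read_id = ids[[i]], seg, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(cbind(data.frame(read_id = character(), stringsAsFactors = FALSE),
                 empty_segments()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
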