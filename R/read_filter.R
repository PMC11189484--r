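#' Structure-filter parameters
#'
#' Thresholds of the three terminal-structure criteria applied to candidate
#' telomeric reads: (1) the read must carry the motif in the orientation of
#' a chromosome terminus — the C-strand form (CCCTAA) opening the read or
#' the G-strand form (TTAGGG) closing it; (2) that terminal tract must sit
#' within `terminus_window` bp of the read end; (3) at least `min_anchor`
#' bp of contiguous non-telomeric (subtelomeric) sequence must lie
#' immediately interior to the tract.
#'
#' @param terminus_window Maximum distance (bp) between the terminal tract
#'   and the read end for criterion 2. Default 200.
#' @param min_anchor Minimum contiguous non-telomeric anchor (bp) interior
#'   to the tract. Default 60.
#' @param terminal_search Coarse terminal zone (bp) within which a tract is
#'   considered terminal at all for criterion 1; tracts further inside the
#'   read are interstitial. Default 500.
#' @param chain_gap Maximum breakpoint (bp) when chaining segments into one
#'   tract for the anchor measurement; kept equal to the concatenation
#'   rule's 250 bp default.
#' @param min_mean_q Minimum mean base quality (Phred) when qualities are
#'   supplied. Default 9.
#' @param require_terminal_motif Whether criterion 1 is enforced. Default TRUE.
#' @return An object of class `"filter_params"`.
#' @export
filter_params <- function(terminus_window = 200L, min_anchor = 60L,
                          terminal_search = 500L, chain_gap = 250L,
                          min_mean_q = 9, require_terminal_motif = TRUE) {
  stopifnot(terminus_window > 0, min_anchor > 0, terminal_search > 0,
            chain_gap >= 0)
  structure(list(terminus_window = as.integer(terminus_window),
                 min_anchor = as.integer(min_anchor),
                 terminal_search = as.integer(terminal_search),
                 chain_gap = as.integer(chain_gap),
                 min_mean_q = min_mean_q,
                 require_terminal_motif = isTRUE(require_terminal_motif)),
            class = "filter_params")
}

#' Determine which read terminus carries the telomere motif
#'
#' Criterion 1: a read sequenced off a chromosome end either commences
#' with the 5'-(CCCTAA)n motif or concludes with the 5'-(TTAGGG)n motif.
#' A tract qualifies as terminal when no other segment lies distal to it
#' and its distal flank is at most `params$terminal_search` bp. When both
#' sides qualify the side with the longer tract is reported.
#'
#' @param sequence Read sequence (character scalar).
#' @param segments Segment table from [find_repeat_segments()] for this read.
#' @param params A [filter_params()].
#' @return `"read_start"`, `"read_end"`, or `"none"`.
#' @export
check_terminal_motif <- function(sequence, segments, params = filter_params()) {
  n <- nchar(sequence)
  sides <- terminal_candidates(segments, n, params)
  if (is.null(sides$start) && is.null(sides$end)) return("none")
  if (!is.null(sides$start) && is.null(sides$end)) return("read_start")
  if (is.null(sides$start) && !is.null(sides$end)) return("read_end")
  len_start <- sides$start$end - sides$start$start
  len_end <- sides$end$end - sides$end$start
  if (len_start >= len_end) "read_start" else "read_end"
}

#' Check the terminus-window criterion
#'
#' Criterion 2: the terminal-side tract must start (for `read_start`) or
#' end (for `read_end`) within `params$terminus_window` bp of the
#' corresponding read end.
#'
#' @param segments Segment table for the read.
#' @param terminus `"read_start"` or `"read_end"`.
#' @param read_length Length of the read in bp.
#' @param params A [filter_params()].
#' @return Logical.
#' @export
check_terminus_window <- function(segments, terminus, read_length,
                                  params = filter_params()) {
  stopifnot(terminus %in% c("read_start", "read_end"))
  seg <- terminal_segment(segments, terminus, read_length)
  if (is.null(seg)) return(FALSE)
  if (terminus == "read_start") {
    seg$start <= params$terminus_window
  } else {
    (read_length - seg$end) <= params$terminus_window
  }
}

#' Measure the subtelomeric anchor
#'
#' Criterion 3: the contiguous non-telomeric sequence immediately interior
#' to the terminal telomeric tract, bounded by the next telomeric segment
#' or the far read end. The tract itself is the terminal segment chain
#' under the `chain_gap` breakpoint rule, so short interruptions inside
#' the tract do not count as anchor.
#'
#' @inheritParams check_terminus_window
#' @param sequence Read sequence (used for its length).
#' @return A list with `ok` (logical, anchor >= `params$min_anchor`) and
#'   `anchor_length` (integer bp).
#' @export
check_anchor <- function(sequence, segments, terminus,
                         params = filter_params()) {
  stopifnot(terminus %in% c("read_start", "read_end"))
  n <- nchar(sequence)
  segs <- segments[order(segments$start), , drop = FALSE]
  chain <- chain_terminal_segments(segs, terminus, n, params$chain_gap)
  if (is.null(chain)) {
    return(list(ok = FALSE, anchor_length = 0L))
  }
  if (terminus == "read_start") {
    inner <- chain$end
    after <- segs$start[segs$start >= inner]
    bound <- if (length(after)) min(after) else n
    anchor <- bound - inner
  } else {
    inner <- chain$start
    before <- segs$end[segs$end <= inner]
    bound <- if (length(before)) max(before) else 0L
    anchor <- inner - bound
  }
  list(ok = anchor >= params$min_anchor, anchor_length = as.integer(anchor))
}

#' Apply the three-criteria structure filter to one read
#'
#' Combines [check_terminal_motif()], [check_terminus_window()] and
#' [check_anchor()] into a verdict; every violated criterion is reported
#' (no short-circuiting). Reads with qualifying telomeric tracts at both
#' termini are rejected with reason `both_terminal`, and a mean base
#' quality below `params$min_mean_q` (when `mean_quality` is given) adds
#' `quality_fail`.
#'
#' @param sequence Read sequence.
#' @param segments Segment table for this read.
#' @param params A [filter_params()].
#' @param read_id Identifier copied into the verdict.
#' @param mean_quality Optional mean Phred quality of the read.
#' @return A one-row data.frame: `read_id`, `passed`, `fail_reasons`
#'   (comma-separated, `""` when passed), `terminus`, `anchor_length`.
#' @export
apply_structure_filter <- function(sequence, segments,
                                   params = filter_params(),
                                   read_id = "read", mean_quality = NULL) {
  n <- nchar(sequence)
  reasons <- character()

  if (!is.null(mean_quality) && mean_quality < params$min_mean_q) {
    reasons <- c(reasons, "quality_fail")
  }

  sides <- terminal_candidates(segments, n, params)
  both <- !is.null(sides$start) && !is.null(sides$end)
  terminus <- check_terminal_motif(sequence, segments, params)

  if (terminus == "none") {
    if (params$require_terminal_motif) {
      reasons <- c(reasons, "no_terminal_motif")
    }
    anchor_len <- 0L
  } else {
    if (both) reasons <- c(reasons, "both_terminal")
    if (!check_terminus_window(segments, terminus, n, params)) {
      reasons <- c(reasons, "motif_not_within_terminus_window")
    }
    anc <- check_anchor(sequence, segments, terminus, params)
    anchor_len <- anc$anchor_length
    if (!anc$ok) reasons <- c(reasons, "insufficient_subtelomeric_anchor")
  }

  passed <- length(reasons) == 0L && terminus != "none"
  if (terminus == "none" && !params$require_terminal_motif) passed <- FALSE
  data.frame(read_id = read_id, passed = passed,
             fail_reasons = paste(reasons, collapse = ","),
             terminus = if (passed || terminus != "none") terminus else "none",
             anchor_length = anchor_len, stringsAsFactors = FALSE)
}

#' Structure-filter a set of reads
#'
#' @param reads Named `DNAStringSet` or named character vector.
#' @param segments Batch segment table from [find_repeat_segments_batch()].
#' @param params A [filter_params()].
#' @param mean_qualities Optional named numeric vector of mean Phred
#'   qualities per read.
#' @return A data.frame of verdicts, one row per read.
#' @export
apply_structure_filter_batch <- function(reads, segments,
                                         params = filter_params(),
                                         mean_qualities = NULL) {
  seqs <- as.character(reads)
  ids <- names(seqs) %||% names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    seg <- segments[segments$read_id == ids[[i]], , drop = FALSE]
    q <- if (!is.null(mean_qualities)) unname(mean_qualities[ids[[i]]]) else NULL
    apply_structure_filter(seqs[[i]], seg, params, read_id = ids[[i]],
                           mean_quality = q)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## --- internals -------------------------------------------------------------

# Candidate terminal tracts per side: the distal-most segment on a side
# qualifies if its form matches the side orientation, nothing lies distal
# to it, and its distal flank is within the coarse terminal zone.
terminal_candidates <- function(segments, read_length, params) {
  out <- list(start = NULL, end = NULL)
  if (is.null(segments) || nrow(segments) == 0L) return(out)
  segs <- segments[order(segments$start), , drop = FALSE]
  first <- segs[1, ]
  last <- segs[nrow(segs), ]
  if (first$form == "C" && first$start <= params$terminal_search) {
    out$start <- first
  }
  if (last$form == "G" &&
      (read_length - last$end) <= params$terminal_search) {
    out$end <- last
  }
  out
}

terminal_segment <- function(segments, terminus, read_length) {
  if (is.null(segments) || nrow(segments) == 0L) return(NULL)
  segs <- segments[order(segments$start), , drop = FALSE]
  if (terminus == "read_start") segs[1, ] else segs[nrow(segs), ]
}

# Chain the terminal-side segments inward while breakpoints stay within
# max_gap; returns the merged span or NULL when there is no segment.
chain_terminal_segments <- function(segs, terminus, read_length, max_gap) {
  if (nrow(segs) == 0L) return(NULL)
  if (terminus == "read_end") {
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  }
  span_start <- segs$start[1]
  span_end <- segs$end[1]
  if (nrow(segs) > 1L) {
    for (i in 2:nrow(segs)) {
      gap <- if (terminus == "read_start") {
        segs$start[i] - span_end
      } else {
        span_start - segs$end[i]
      }
      if (gap > max_gap || gap < 0) break
      span_start <- min(span_start, segs$start[i])
      span_end <- max(span_end, segs$end[i])
    }
  }
  list(start = span_start, end = span_end)
}
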