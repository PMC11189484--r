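#' Concatenation-rule parameters
#'
#' A read's telomere length is the span of its terminal segment chain:
#' starting from the terminal-side repeat segment, successive segments of
#' at least `min_segment` bp are chained while the breakpoint between
#' neighbours does not exceed `max_gap` bp. Segments below `min_segment`
#' are treated as noise and removed before gaps are measured.
#'
#' @param min_segment Minimum segment span (bp) to participate. Default 50.
#' @param max_gap Maximum breakpoint (bp) between chained segments.
#'   Default 250.
#' @param length_mode `"span"` (default: first merged base to last,
#'   counting interstitial variant bases toward telomere length) or
#'   `"sum"` (sum of segment spans, for sensitivity analysis).
#' @return An object of class `"concat_params"`.
#' @export
concat_params <- function(min_segment = 50L, max_gap = 250L,
                          length_mode = c("span", "sum")) {
  stopifnot(min_segment > 0, max_gap >= 0)
  length_mode <- match.arg(length_mode)
  structure(list(min_segment = as.integer(min_segment),
                 max_gap = as.integer(max_gap),
                 length_mode = length_mode),
            class = "concat_params")
}

#' Call telomere length for one structure-passing read
#'
#' Applies the segment-concatenation rule from the terminal side inward:
#' chains segments whose inter-segment gap is at most `params$max_gap`,
#' ignoring segments shorter than `params$min_segment`, and stops at the
#' first larger breakpoint. The called length is the merged span
#' (including internal gaps) by default.
#'
#' @param verdict One-row verdict from [apply_structure_filter()]; must
#'   have `passed == TRUE`.
#' @param segments Segment table for the read.
#' @param params A [concat_params()].
#' @param read_length Read length in bp (used to orient chaining from the
#'   3' terminus).
#' @return A one-row data.frame: `read_id`, `telomere_length`,
#'   `n_segments_merged`, `span_start`, `span_end`, `terminus`.
#' @export
#' @examples
#' segs <- data.frame(start = c(0L, 3100L), end = c(3000L, 5000L),
#'                    form = "C", identity = 0.98, score = c(2500L, 1500L))
#' v <- data.frame(read_id = "r", passed = TRUE, fail_reasons = "",
#'                 terminus = "read_start", anchor_length = 2000L)
#' call_telomere_length(v, segs, read_length = 7000L)$telomere_length  # 5000
call_telomere_length <- function(verdict, segments,
                                 params = concat_params(),
                                 read_length = NULL) {
  if (!isTRUE(verdict$passed)) {
    stop("call_telomere_length requires a passing structure verdict")
  }
  terminus <- verdict$terminus
  segs <- segments[(segments$end - segments$start) >= params$min_segment, ,
                   drop = FALSE]
  segs <- segs[order(segs$start), , drop = FALSE]
  if (nrow(segs) == 0L) stop("no segments above min_segment for a passing read")
  if (is.null(read_length)) read_length <- max(segs$end)

  idx <- if (terminus == "read_start") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  segs <- segs[idx, , drop = FALSE]

  merged_start <- segs$start[1]
  merged_end <- segs$end[1]
  n_merged <- 1L
  sum_len <- segs$end[1] - segs$start[1]
  if (nrow(segs) > 1L) {
    for (i in 2:nrow(segs)) {
      gap <- if (terminus == "read_start") {
        segs$start[i] - merged_end
      } else {
        merged_start - segs$end[i]
      }
      if (gap < 0 || gap > params$max_gap) break
      merged_start <- min(merged_start, segs$start[i])
      merged_end <- max(merged_end, segs$end[i])
      sum_len <- sum_len + (segs$end[i] - segs$start[i])
      n_merged <- n_merged + 1L
    }
  }
  len <- if (params$length_mode == "span") merged_end - merged_start else sum_len
  data.frame(read_id = verdict$read_id,
             telomere_length = as.integer(len),
             n_segments_merged = n_merged,
             span_start = as.integer(merged_start),
             span_end = as.integer(merged_end),
             terminus = terminus, stringsAsFactors = FALSE)
}

#' Call telomere lengths for a batch of reads
#'
#' @param verdicts Verdict table from [apply_structure_filter_batch()];
#'   only passing rows are called.
#' @param segments Batch segment table.
#' @param params A [concat_params()].
#' @param read_lengths Optional named integer vector of read lengths.
#' @return A data.frame of telomere calls with the verdict's
#'   `anchor_length` joined on.
#' @export
call_telomere_lengths <- function(verdicts, segments,
                                  params = concat_params(),
                                  read_lengths = NULL) {
  pass <- verdicts[verdicts$passed, , drop = FALSE]
  out <- lapply(seq_len(nrow(pass)), function(i) {
    v <- pass[i, ]
    seg <- segments[segments$read_id == v$read_id, , drop = FALSE]
    rl <- if (!is.null(read_lengths)) unname(read_lengths[v$read_id]) else NULL
    call_telomere_length(v, seg, params, read_length = rl)
  })
  if (length(out) == 0L) {
    return(data.frame(read_id = character(), telomere_length = integer(),
                      n_segments_merged = integer(), span_start = integer(),
                      span_end = integer(), terminus = character(),
                      anchor_length = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$anchor_length <- pass$anchor_length[match(res$read_id, pass$read_id)]
  rownames(res) <- NULL
  res
}
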