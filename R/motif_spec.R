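#' Telomere motif specification
#'
#' Parameters of the noise-tolerant repeat finder: the canonical telomeric
#' motif, its reverse complement (the C-strand form), the identity and
#' length thresholds a reported segment must meet, and the alignment
#' scoring scheme used by the wraparound dynamic program.
#'
#' The vertebrate telomere repeat is 5'-TTAGGG-3' on the G-rich strand;
#' a read sequenced from the opposite strand shows the 5'-CCCTAA-3' form.
#' Segments shorter than `min_segment_length` (default 50 bp, matching the
#' segment-concatenation rule) or below `min_identity` are not emitted.
#'
#' @param canonical_motif G-strand motif (default `"TTAGGG"`).
#' @param min_identity Minimum fraction of matching alignment columns in an
#'   emitted segment, in (0, 1]. Default 0.85.
#' @param min_segment_length Minimum read-span of an emitted segment in bp;
#'   must be at least the motif length. Default 50.
#' @param match,mismatch,gap Integer alignment scores (mismatch and gap
#'   negative). Defaults +1/-5/-5.
#'
#' @return An object of class `"motif_spec"`.
#' @export
#' @examples
#' spec <- motif_spec()
#' spec$complement_motif  # "CCCTAA"
motif_spec <- function(canonical_motif = "TTAGGG",
                       min_identity = 0.85,
                       min_segment_length = 50L,
                       match = 1L, mismatch = -5L, gap = -5L) {
  canonical_motif <- toupper(canonical_motif)
  stopifnot(nchar(canonical_motif) >= 2,
            !grepl("[^ACGT]", canonical_motif),
            is.numeric(min_identity), min_identity > 0, min_identity <= 1,
            min_segment_length >= nchar(canonical_motif),
            match > 0, mismatch < 0, gap < 0)
  complement <- revcomp_string(canonical_motif)
  structure(list(
    canonical_motif = canonical_motif,
    complement_motif = complement,
    min_identity = min_identity,
    min_segment_length = as.integer(min_segment_length),
    match = as.integer(match),
    mismatch = as.integer(mismatch),
    gap = as.integer(gap)
  ), class = "motif_spec")
}

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over A/C/G/T/N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("Telomere motif spec:", x$canonical_motif, "/", x$complement_motif, "\n")
  cat(sprintf("  min identity %.2f, min segment %d bp, scores %d/%d/%d\n",
              x$min_identity, x$min_segment_length, x$match, x$mismatch, x$gap))
  invisible(x)
}
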