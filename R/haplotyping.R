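#' Allele assignment against a phased diploid reference
#'
#' When the pangenome was built from a phased assembly (maternal and
#' paternal contigs), each arm assignment already carries the contig's
#' parental label; this step keeps assignments with mapping quality
#' strictly greater than `min_mapq` (default 5) and returns them as
#' allele-labelled. Arms absent after the filter are simply absent from
#' the table (not reported as zero-length).
#'
#' @param assignments Assignment table from [select_alignments()].
#' @param min_mapq Strict lower MAPQ bound; reads with `mapq <= min_mapq`
#'   are dropped. Default 5.
#' @return The allele-labelled assignment table.
#' @export
assign_haplotype_phased <- function(assignments, min_mapq = 5L) {
  if (nrow(assignments) > 0L && all(assignments$haplotype == "unphased")) {
    stop("reference is not phased; use the de novo route ",
         "(cross_reference_denovo)")
  }
  assignments[assignments$mapq > min_mapq &
                assignments$haplotype != "unphased", , drop = FALSE]
}

#' Cross-reference external haplotags with pangenome arm assignments
#'
#' The de novo phasing route: an external variant-call/phase/haplotag
#' toolchain (run against a haploid reference) produces per-read H1/H2
#' tags; these are joined to the pangenome arm assignments, keeping only
#' reads that match exactly on read id, chromosome, arm, and strand.
#' Reads with conflicting duplicate keys are excluded. Unmatched reads
#' stay in bulk tables but receive no allele label.
#'
#' @param haplotags data.frame with `read_id`, `haplotype_tag`
#'   (`"H1"`/`"H2"`/`"untagged"`), `chromosome`, `arm`, `strand`.
#' @param assignments Pangenome assignment table
#'   (from [select_alignments()]).
#' @return Assignment rows that matched, with a `haplotype_tag` column.
#' @export
cross_reference_denovo <- function(haplotags, assignments) {
  ht <- haplotags[haplotags$haplotype_tag %in% c("H1", "H2"), , drop = FALSE]
  key <- function(d) paste(d$read_id, d$chromosome, d$arm, d$strand,
                           sep = "\r")
  # a read tagged with conflicting keys or tags is unusable
  dup <- unique(ht$read_id[duplicated(ht$read_id)])
  if (length(dup)) {
    per_read_keys <- tapply(paste(key(ht), ht$haplotype_tag),
                            ht$read_id, function(x) length(unique(x)))
    conflicted <- names(per_read_keys)[per_read_keys > 1]
    ht <- ht[!ht$read_id %in% conflicted, , drop = FALSE]
    ht <- ht[!duplicated(ht$read_id), , drop = FALSE]
  }
  idx <- match(key(assignments), key(ht))
  out <- assignments[!is.na(idx), , drop = FALSE]
  out$haplotype_tag <- ht$haplotype_tag[idx[!is.na(idx)]]
  rownames(out) <- NULL
  out
}

#' Fixture haplotagger for tests and simulations
#'
#' Stands in for the external variant-calling/phasing toolchain on
#' simulated data: tags each read from its known source haplotype in the
#' simulation truth table (maternal = H1, paternal = H2). The strand and
#' arm reported are taken from the supplied assignment table, emulating a
#' haplotagger run on the same alignments.
#'
#' @param truth Simulation truth table from [simulate_reads()].
#' @param assignments Assignment table supplying chromosome/arm/strand.
#' @return A haplotag table usable with [cross_reference_denovo()].
#' @export
fixture_haplotagger <- function(truth, assignments) {
  idx <- match(assignments$read_id, truth$read_id)
  keep <- !is.na(idx)
  data.frame(read_id = assignments$read_id[keep],
             haplotype_tag = ifelse(truth$haplotype[idx[keep]] == "maternal",
                                    "H1", "H2"),
             chromosome = assignments$chromosome[keep],
             arm = assignments$arm[keep],
             strand = assignments$strand[keep],
             stringsAsFactors = FALSE)
}
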