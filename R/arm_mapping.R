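#' Build a pangenome chromosome-end reference
#'
#' Extracts chromosome-end records from one or more telomere-to-telomere
#' assemblies and annotates each record with its telomere and subtelomere
#' intervals. In `"end"` mode every contig yields two records — the first
#' and last `end_length` bases, named `assembly#contig#p` and
#' `assembly#contig#q` (p = contig start) — while `"whole"` mode keeps
#' contigs intact and annotates both ends of each contig. The telomere
#' interval of a record is located by running the repeat finder on the
#' reference sequence itself and chaining terminal segments; the
#' subtelomere is the adjacent non-telomeric remainder (capped at
#' `end_length`).
#'
#' @param assemblies Named list of assemblies; each element is a
#'   `"synthetic_assembly"`, a [Biostrings::DNAStringSet], or a FASTA
#'   path. Names are used as assembly ids (a `"synthetic_assembly"`
#'   carries its own id).
#' @param end_length Bases retained from each contig end. Default 25000.
#' @param mode `"end"` (extract ends) or `"whole"` (retain contigs).
#' @param haplotype_tokens Named character vector mapping parental labels
#'   to contig-name substrings, e.g.
#'   `c(maternal = "maternal", paternal = "paternal")`.
#' @param spec [motif_spec()] used to locate reference telomere tracts.
#' @param chain_gap Breakpoint tolerance (bp) when chaining reference
#'   telomere segments. Default 250.
#' @return An object of class `"pangenome_reference"`: `sequences` (named
#'   `DNAStringSet` of records) and `regions` (data.frame with one row per
#'   record end: record, assembly, contig, chromosome, haplotype, arm,
#'   `telo_start`/`telo_end` and `subtel_start`/`subtel_end` in 0-based
#'   half-open record coordinates).
#' @export
build_pangenome <- function(assemblies, end_length = 25000L,
                            mode = c("end", "whole"),
                            haplotype_tokens = c(maternal = "maternal",
                                                 paternal = "paternal"),
                            spec = motif_spec(), chain_gap = 250L) {
  mode <- match.arg(mode)
  if (inherits(assemblies, "synthetic_assembly") ||
      is(assemblies, "DNAStringSet") || is.character(assemblies)) {
    assemblies <- list(assemblies)
  }
  seq_out <- list()
  reg <- list()
  for (ai in seq_along(assemblies)) {
    a <- assemblies[[ai]]
    aid <- names(assemblies)[ai]
    if (inherits(a, "synthetic_assembly")) {
      contigs <- a$sequences
      if (is.null(aid) || !nzchar(aid)) aid <- a$assembly_id
    } else if (is.character(a)) {
      contigs <- Biostrings::readDNAStringSet(a)
      names(contigs) <- sub("\\s.*$", "", names(contigs))
    } else {
      contigs <- a
    }
    if (is.null(aid) || !nzchar(aid)) aid <- paste0("asm", ai)
    for (cn in names(contigs)) {
      cseq <- as.character(contigs[[cn]])
      clen <- nchar(cseq)
      hap <- parse_haplotype(cn, haplotype_tokens)
      chrom <- strip_haplotype_token(cn, haplotype_tokens)
      if (mode == "end") {
        if (clen < 2L * end_length) {
          warning("contig ", cn, " shorter than 2x end_length; ",
                  "p and q records overlap")
        }
        p_seq <- substr(cseq, 1L, min(end_length, clen))
        q_seq <- substr(cseq, max(1L, clen - end_length + 1L), clen)
        for (arm in c("p", "q")) {
          rec <- paste0(aid, "#", cn, "#", arm)
          rseq <- if (arm == "p") p_seq else q_seq
          seq_out[[rec]] <- rseq
          reg[[length(reg) + 1L]] <-
            annotate_record_end(rec, rseq, arm, aid, cn, chrom, hap,
                                spec, chain_gap, end_length)
        }
      } else {
        rec <- paste0(aid, "#", cn)
        seq_out[[rec]] <- cseq
        for (arm in c("p", "q")) {
          reg[[length(reg) + 1L]] <-
            annotate_record_end(rec, cseq, arm, aid, cn, chrom, hap,
                                spec, chain_gap, end_length)
        }
      }
    }
  }
  regions <- do.call(rbind, reg)
  rownames(regions) <- NULL
  structure(list(sequences = Biostrings::DNAStringSet(unlist(seq_out)),
                 regions = regions,
                 end_length = as.integer(end_length), mode = mode),
            class = "pangenome_reference")
}

#' Ingest alignment records from a SAM or BAM file
#'
#' Reads mapped records with [GenomicAlignments::readGAlignments()]
#' (SAM input is converted with [Rsamtools::asBam()]) and returns a flat
#' table in 0-based half-open reference coordinates, with the SAM flag
#' decoded into the primary/secondary/supplementary rank used by the
#' alignment-selection rule.
#'
#' @param path SAM or BAM file.
#' @return data.frame: `read_id`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `mapq`, `rank`, `order` (file order).
#' @export
read_alignment_records <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE, overwrite = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  mc <- S4Vectors::mcols(ga)
  flag <- mc$flag
  rank <- ifelse(bitwAnd(flag, 2048L) > 0L, "supplementary",
                 ifelse(bitwAnd(flag, 256L) > 0L, "secondary", "primary"))
  data.frame(read_id = mc$qname,
             contig = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)),
             mapq = mc$mapq, rank = rank,
             order = seq_along(ga), stringsAsFactors = FALSE)
}

#' Select the telomere-informative alignment per read
#'
#' Alignments are ranked primary > secondary (supplementary records are
#' never used). A primary alignment intersecting the subtelomere or
#' telomere region of its record is kept; otherwise secondary alignments
#' are scanned in deterministic order (MAPQ descending, then file order,
#' then record name) and the first that intersects an annotated region is
#' promoted to the read's assignment. Reads with no intersecting
#' alignment are unassigned.
#'
#' @param alignments Table from [read_alignment_records()].
#' @param reference A `"pangenome_reference"`.
#' @param min_overlap Minimum overlap (bp) with a region to count as an
#'   intersection. Default 1.
#' @return data.frame with one row per assigned read: `read_id`,
#'   `assembly`, `chromosome`, `arm`, `haplotype`, `record`, `mapq`,
#'   `strand`, `promotion` (`"primary_kept"` or `"secondary_promoted"`).
#' @export
select_alignments <- function(alignments, reference, min_overlap = 1L) {
  stopifnot(inherits(reference, "pangenome_reference"))
  regions <- reference$regions
  out <- list()
  for (rid in unique(alignments$read_id)) {
    recs <- alignments[alignments$read_id == rid, , drop = FALSE]
    prim <- recs[recs$rank == "primary", , drop = FALSE]
    sec <- recs[recs$rank == "secondary", , drop = FALSE]
    if (nrow(sec) > 1L) {
      sec <- sec[order(-sec$mapq, sec$order, sec$contig), , drop = FALSE]
    }
    hit <- NULL; promotion <- NULL
    if (nrow(prim) > 0L) {
      h <- region_hit(prim[1, ], regions, min_overlap)
      if (!is.null(h)) { hit <- list(aln = prim[1, ], region = h)
                         promotion <- "primary_kept" }
    }
    if (is.null(hit) && nrow(sec) > 0L) {
      for (i in seq_len(nrow(sec))) {
        h <- region_hit(sec[i, ], regions, min_overlap)
        if (!is.null(h)) { hit <- list(aln = sec[i, ], region = h)
                           promotion <- "secondary_promoted"; break }
      }
    }
    if (is.null(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = rid, assembly = hit$region$assembly,
      chromosome = hit$region$chromosome, arm = hit$region$arm,
      haplotype = hit$region$haplotype, record = hit$region$record,
      mapq = hit$aln$mapq, strand = hit$aln$strand,
      promotion = promotion, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(), assembly = character(),
                      chromosome = character(), arm = character(),
                      haplotype = character(), record = character(),
                      mapq = integer(), strand = character(),
                      promotion = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter arm assignments by mapping quality
#'
#' Default threshold 20; the cancer profile uses 10.
#'
#' @param assignments Assignment table from [select_alignments()].
#' @param threshold Minimum MAPQ (inclusive). Default 20.
#' @return The filtered assignment table.
#' @export
filter_by_mapq <- function(assignments, threshold = 20L) {
  stopifnot(threshold >= 0)
  assignments[assignments$mapq >= threshold, , drop = FALSE]
}

#' Normalized per-arm coverage
#'
#' Fraction of assigned telomeric reads per chromosome arm; assignments
#' are expected to be MAPQ-filtered (>= 20) already.
#'
#' @param assignments Filtered assignment table.
#' @return data.frame: `chromosome`, `arm`, `n_reads`, `fraction`
#'   (summing to 1 over arms); empty with a warning when no reads are
#'   assigned.
#' @export
normalized_coverage <- function(assignments) {
  if (nrow(assignments) == 0L) {
    warning("no assigned reads; coverage table is empty")
    return(data.frame(chromosome = character(), arm = character(),
                      n_reads = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste0(assignments$chromosome, "#", assignments$arm)
  tab <- table(key)
  parts <- strsplit(names(tab), "#", fixed = TRUE)
  data.frame(chromosome = vapply(parts, `[`, "", 1),
             arm = vapply(parts, `[`, "", 2),
             n_reads = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Align reads to a pangenome reference with minimap2
#'
#' Thin wrapper over the external long-read aligner: writes the reference
#' when needed and runs `minimap2 -x map-ont -N 2 -Y -L -a` so that
#' secondary alignments are retained and sequences are soft-clipped.
#' Requires `minimap2` on the PATH.
#'
#' On a chromosome-end reference the telomeric repeat dominates the
#' minimizer table, and the default fractional repeat filter keeps those
#' seeds, which makes chaining of repeat-only read spans intractable;
#' `occ_cutoff` therefore drops minimizers above an absolute occurrence
#' count (default 50) so that alignments are anchored by the unique
#' subtelomeres.
#'
#' @param reads_fastq Path to the (optionally gzipped) FASTQ of reads.
#' @param reference A `"pangenome_reference"` or a FASTA path.
#' @param out_sam Output SAM path (default: a tempfile).
#' @param occ_cutoff Absolute minimizer-occurrence cutoff passed as
#'   `-f`; set `NULL` to keep minimap2's default fractional filter.
#' @param extra_args Additional minimap2 arguments.
#' @return The SAM path, invisibly usable with
#'   [read_alignment_records()].
#' @export
align_reads <- function(reads_fastq, reference,
                        out_sam = tempfile(fileext = ".sam"),
                        occ_cutoff = 50L,
                        extra_args = character()) {
  mm2 <- Sys.which("minimap2")
  if (!nzchar(mm2)) stop("minimap2 not found on PATH")
  ref_fa <- if (inherits(reference, "pangenome_reference")) {
    fa <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(reference$sequences, fa)
    fa
  } else reference
  occ <- if (!is.null(occ_cutoff)) c("-f", as.character(occ_cutoff))
  args <- c("-x", "map-ont", occ, "-N", "2", "-Y", "-L", "-a", extra_args,
            ref_fa, reads_fastq)
  status <- system2(mm2, args, stdout = out_sam, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  invisible(out_sam)
}

## --- internals -------------------------------------------------------------

parse_haplotype <- function(contig, tokens) {
  lc <- tolower(contig)
  for (lab in names(tokens)) {
    if (grepl(tolower(tokens[[lab]]), lc, fixed = TRUE)) return(lab)
  }
  "unphased"
}

strip_haplotype_token <- function(contig, tokens) {
  out <- contig
  for (tok in tokens) {
    out <- sub(paste0("[._-]?", tok), "", out, ignore.case = TRUE)
  }
  out
}

# Locate a record end's telomere tract with the repeat finder and derive
# the adjacent subtelomere interval (0-based half-open record coords).
annotate_record_end <- function(record, rseq, arm, assembly, contig,
                                chromosome, haplotype, spec, chain_gap,
                                end_length) {
  n <- nchar(rseq)
  segs <- find_repeat_segments(rseq, spec)
  expected_form <- if (arm == "p") "C" else "G"
  segs <- segs[segs$form == expected_form, , drop = FALSE]
  terminus <- if (arm == "p") "read_start" else "read_end"
  chain <- chain_terminal_segments(segs, terminus, n, chain_gap)
  near_ok <- !is.null(chain) &&
    ((arm == "p" && chain$start <= chain_gap) ||
     (arm == "q" && (n - chain$end) <= chain_gap))
  if (near_ok) {
    telo_start <- chain$start; telo_end <- chain$end
  } else if (arm == "p") {
    telo_start <- 0L; telo_end <- 0L
  } else {
    telo_start <- n; telo_end <- n
  }
  if (arm == "p") {
    subtel_start <- telo_end
    subtel_end <- min(n, telo_end + end_length)
  } else {
    subtel_end <- telo_start
    subtel_start <- max(0L, telo_start - end_length)
  }
  data.frame(record = record, assembly = assembly, contig = contig,
             chromosome = chromosome, haplotype = haplotype, arm = arm,
             telo_start = as.integer(telo_start),
             telo_end = as.integer(telo_end),
             subtel_start = as.integer(subtel_start),
             subtel_end = as.integer(subtel_end),
             record_length = as.integer(n), stringsAsFactors = FALSE)
}

# the arm whose telomere+subtelomere annotation overlaps the alignment
# most wins; ties go to the first annotated row for determinism
region_hit <- function(aln, regions, min_overlap) {
  cand <- regions[regions$record == aln$contig, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ov <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, ]
    max(0, min(aln$end, r$telo_end) - max(aln$start, r$telo_start)) +
      max(0, min(aln$end, r$subtel_end) - max(aln$start, r$subtel_start))
  }, numeric(1))
  if (max(ov) < min_overlap) return(NULL)
  cand[which.max(ov), ]
}
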