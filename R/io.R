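#' Read sequencing reads from FASTA or FASTQ
#'
#' Gzip-transparent; the format is taken from the file extension
#' (`.fq`/`.fastq` vs anything else). For FASTQ, per-read mean Phred
#' qualities are returned alongside the sequences.
#'
#' @param path Input file.
#' @return List with `sequences` (named character vector, names truncated
#'   at the first whitespace) and `mean_qualities` (named numeric vector,
#'   or `NULL` for FASTA).
#' @export
read_reads <- function(path) {
  is_fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (is_fastq) {
    qs <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
      error = function(e) NULL)
    if (is.null(qs) || length(qs) == 0L) {
      return(list(sequences = setNames(character(0), character(0)),
                  mean_qualities = setNames(numeric(0), character(0))))
    }
    seqs <- as.character(qs)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    qual <- methods::as(Biostrings::quality(qs), "IntegerList")
    mq <- vapply(qual, function(v) mean(as.numeric(v)), numeric(1))
    names(mq) <- names(seqs)
    list(sequences = seqs, mean_qualities = mq)
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    list(sequences = seqs, mean_qualities = NULL)
  }
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Output path (`.gz` compresses).
#' @param quality_char Flat per-base quality character. Default `"5"`
#'   (Phred 20).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "5") {
  dss <- Biostrings::DNAStringSet(unlist(as.list(reads)))
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep(quality_char, n)
  }, character(1)))
  qdss <- Biostrings::QualityScaledDNAStringSet(
    dss, Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(
    qdss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a pangenome reference as FASTA plus BED region annotations
#'
#' The BED file holds one interval per annotated region, named
#' `telomere` or `subtelomere`, in standard 0-based half-open BED
#' coordinates; zero-width telomere intervals are omitted.
#'
#' @param reference A `"pangenome_reference"`.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_pangenome <- function(reference, fasta_path, bed_path) {
  stopifnot(inherits(reference, "pangenome_reference"))
  write_fasta(reference$sequences, fasta_path)
  reg <- reference$regions
  rows <- list()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    if (r$telo_end > r$telo_start) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$record, start = r$telo_start, end = r$telo_end,
        name = "telomere", stringsAsFactors = FALSE)
    }
    if (r$subtel_end > r$subtel_start) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$record, start = r$subtel_start, end = r$subtel_end,
        name = "subtelomere", stringsAsFactors = FALSE)
    }
  }
  bed <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    name = bed$name)
  rtracklayer::export(gr, bed_path, format = "BED")
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' Load a pangenome reference from FASTA plus BED
#'
#' Inverse of [write_pangenome()] for references whose record names
#' follow the `assembly#contig#arm` convention.
#'
#' @param fasta_path,bed_path Paths written by [write_pangenome()].
#' @param haplotype_tokens As in [build_pangenome()].
#' @return A `"pangenome_reference"`.
#' @export
load_pangenome <- function(fasta_path, bed_path,
                           haplotype_tokens = c(maternal = "maternal",
                                                paternal = "paternal")) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(bed_path, format = "BED")
  bed <- data.frame(record = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    name = gr$name, stringsAsFactors = FALSE)
  recs <- unique(bed$record)
  rows <- lapply(recs, function(rec) {
    parts <- strsplit(rec, "#", fixed = TRUE)[[1]]
    aid <- parts[1]
    contig <- if (length(parts) >= 2) parts[2] else rec
    arm <- if (length(parts) >= 3) parts[3] else "p"
    b <- bed[bed$record == rec, , drop = FALSE]
    telo <- b[b$name == "telomere", , drop = FALSE]
    sub <- b[b$name == "subtelomere", , drop = FALSE]
    n <- nchar(as.character(seqs[[rec]]))
    ts <- if (nrow(telo)) telo$start[1] else if (arm == "p") 0L else n
    te <- if (nrow(telo)) telo$end[1] else ts
    data.frame(record = rec, assembly = aid, contig = contig,
               chromosome = strip_haplotype_token(contig, haplotype_tokens),
               haplotype = parse_haplotype(contig, haplotype_tokens),
               arm = arm, telo_start = ts, telo_end = te,
               subtel_start = if (nrow(sub)) sub$start[1] else 0L,
               subtel_end = if (nrow(sub)) sub$end[1] else 0L,
               record_length = n, stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  rownames(regions) <- NULL
  structure(list(sequences = seqs, regions = regions,
                 end_length = NA_integer_, mode = "end"),
            class = "pangenome_reference")
}

#' Write a result table as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config_hash Optional configuration hash recorded in a `#`
#'   comment line.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(paste0("# telotape config_hash=", config_hash), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
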