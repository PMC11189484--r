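#' Simulation parameters
#'
#' Defaults reproduce the validation regime used throughout the package:
#' telomeres randomly trimmed by 0 to 3000 bp, 30 reads per chromosome end
#' (30x per-arm coverage), a 2% average error rate, and virtual digestion
#' at the EcoRV site GATATC (blunt cut GAT^ATC, offset 3).
#'
#' @param trim_range Length-2 numeric, uniform telomere-trimming range in
#'   bp. Default `c(0, 3000)`.
#' @param reads_per_end Reads simulated per chromosome end. Default 30.
#' @param error_rate Average per-base error rate. Default 0.02.
#' @param error_mix Substitution/insertion/deletion fractions summing to 1.
#'   Default `c(0.5, 0.25, 0.25)`.
#' @param restriction_site Recognition sequence of the virtual digest.
#'   Default `"GATATC"` (EcoRV).
#' @param cut_offset Cut position within the site (0..site length).
#'   Default 3 (blunt).
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(trim_range = c(0, 3000), reads_per_end = 30L,
                       error_rate = 0.02,
                       error_mix = c(substitution = 0.5, insertion = 0.25,
                                     deletion = 0.25),
                       restriction_site = "GATATC", cut_offset = 3L,
                       seed = 1L) {
  stopifnot(length(trim_range) == 2, trim_range[1] <= trim_range[2],
            reads_per_end >= 1, error_rate >= 0, error_rate < 1,
            abs(sum(error_mix) - 1) < 1e-9, nchar(restriction_site) >= 1,
            cut_offset >= 0, cut_offset <= nchar(restriction_site))
  structure(list(trim_range = trim_range,
                 reads_per_end = as.integer(reads_per_end),
                 error_rate = error_rate, error_mix = error_mix,
                 restriction_site = toupper(restriction_site),
                 cut_offset = as.integer(cut_offset),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Synthesize a truth-known assembly with telomeric chromosome ends
#'
#' Builds synthetic chromosomes of the form
#' `(CCCTAA)n + unique subtelomere + interior + unique subtelomere + (TTAGGG)n`,
#' one unique random subtelomere per arm (and per haplotype in diploid
#' mode). One restriction site is planted mid-interior and the site is
#' scrubbed from subtelomeres, so virtual digestion leaves the full
#' subtelomeric anchor on every simulated read. Telomere tract lengths are
#' drawn from a named sampler. Diploid mode emits maternal and paternal
#' copies whose subtelomeres differ by planted substitutions.
#'
#' @param n_chromosomes Number of chromosomes (each contributes a p and a
#'   q end per haplotype). Default 23.
#' @param subtelomere_length Unique subtelomere length in bp. Default 2500.
#' @param telomere_sampler List describing the tract-length distribution:
#'   `list(dist = "fixed", length =)`, `list(dist = "uniform", min =, max =)`,
#'   or `list(dist = "lognormal", meanlog =, sdlog =)`.
#' @param interior_length Non-subtelomeric interior per chromosome in bp.
#'   Default 600.
#' @param diploid Emit two haplotypes per chromosome. Default FALSE.
#' @param divergence Substitution rate between haplotype subtelomeres in
#'   diploid mode. Default 1/500.
#' @param restriction_site Site planted mid-interior and scrubbed from
#'   subtelomeres. Default `"GATATC"`.
#' @param assembly_id Label recorded in truth tables. Default `"SYN"`.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_assembly"`: `sequences`
#'   (named [Biostrings::DNAStringSet]) and `arms` (truth table with one
#'   row per chromosome end: contig, assembly, chromosome, haplotype, arm,
#'   telomere length, subtelomere interval in contig coordinates).
#' @export
synthesize_genome_ends <- function(n_chromosomes = 23L,
                                   subtelomere_length = 2500L,
                                   telomere_sampler = list(dist = "fixed",
                                                           length = 5000L),
                                   interior_length = 600L,
                                   diploid = FALSE,
                                   divergence = 1 / 500,
                                   restriction_site = "GATATC",
                                   assembly_id = "SYN",
                                   seed = 1L) {
  set.seed(seed)
  haplos <- if (diploid) c("maternal", "paternal") else "unphased"
  seqs <- list()
  rows <- list()
  for (ci in seq_len(n_chromosomes)) {
    chrom <- paste0("chr", ci)
    base_sub_p <- random_dna(subtelomere_length, avoid = restriction_site)
    base_sub_q <- random_dna(subtelomere_length, avoid = restriction_site)
    for (h in haplos) {
      sub_p <- base_sub_p
      sub_q <- base_sub_q
      if (diploid && h == "paternal") {
        sub_p <- mutate_dna(sub_p, divergence, avoid = restriction_site)
        sub_q <- mutate_dna(sub_q, divergence, avoid = restriction_site)
      }
      lp <- sample_tract_length(telomere_sampler)
      lq <- sample_tract_length(telomere_sampler)
      telo_p <- substr(strrep("CCCTAA", ceiling(lp / 6)), 1L, lp)
      telo_q <- substr(strrep("TTAGGG", ceiling(lq / 6)), 1L, lq)
      # a subtelomere must not continue the repeat phase across the
      # junction (the planted tract boundary would be ill-defined), and
      # the junction must stay free of the restriction site
      sub_p <- fix_junction(sub_p, telo_p, "CCCTAA", phase = lp,
                            site = restriction_site)
      # the q tract always abuts its subtelomere at motif phase 0 (only
      # the distal tip is truncated), so the barrier phase is fixed
      sub_q <- revcomp_string(
        fix_junction(revcomp_string(sub_q), telo_q, "CCCTAA", phase = 0L,
                     site = restriction_site))
      half <- floor(interior_length / 2)
      interior <- paste0(random_dna(half, avoid = restriction_site),
                         restriction_site,
                         random_dna(interior_length - half,
                                    avoid = restriction_site))
      contig_seq <- paste0(telo_p, sub_p, interior, sub_q, telo_q)
      contig <- if (diploid) paste0(chrom, "_", h) else chrom
      seqs[[contig]] <- contig_seq
      clen <- nchar(contig_seq)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, assembly = assembly_id, chromosome = chrom,
        haplotype = h, arm = c("p", "q"),
        telomere_length = c(lp, lq),
        subtel_start = c(lp, clen - lq - nchar(sub_q)),
        subtel_end = c(lp + nchar(sub_p), clen - lq),
        contig_length = clen, stringsAsFactors = FALSE)
    }
  }
  arms <- do.call(rbind, rows)
  rownames(arms) <- NULL
  structure(list(
    sequences = Biostrings::DNAStringSet(unlist(seqs)),
    arms = arms, assembly_id = assembly_id, diploid = diploid
  ), class = "synthetic_assembly")
}

#' Virtually digest a sequence at a restriction site
#'
#' Cuts at every occurrence of `site` (between `cut_offset` and
#' `cut_offset + 1` within the site; EcoRV GAT^ATC by default) and reports
#' all fragments plus the one containing the telomeric terminus.
#'
#' @param sequence DNA string.
#' @param site Recognition sequence. Default `"GATATC"`.
#' @param cut_offset Cut position within the site. Default 3.
#' @param telomere_end Which end of `sequence` carries the telomere
#'   (`"start"` or `"end"`); selects the retained fragment.
#' @return List with `fragments` (character vector, in order) and
#'   `retained` (the terminal-most fragment on the telomere side).
#' @export
#' @examples
#' virtual_digest(paste0(strrep("A", 10), "GATATC", strrep("C", 10)))$fragments
virtual_digest <- function(sequence, site = "GATATC", cut_offset = 3L,
                           telomere_end = c("start", "end")) {
  telomere_end <- match.arg(telomere_end)
  stopifnot(nchar(site) >= 1)
  hits <- gregexpr(site, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    return(list(fragments = sequence, retained = sequence))
  }
  cuts <- as.integer(hits) - 1L + cut_offset      # 0-based cut points
  bounds <- c(0L, sort(unique(cuts)), nchar(sequence))
  frags <- substring(sequence, head(bounds, -1) + 1L, tail(bounds, -1))
  frags <- frags[nchar(frags) > 0]
  retained <- if (telomere_end == "start") frags[1] else frags[length(frags)]
  list(fragments = frags, retained = retained)
}

#' Simulate telomeric nanopore-like reads from chromosome ends
#'
#' For every chromosome end of a synthetic assembly, emits
#' `params$reads_per_end` reads: the end sequence oriented telomere-first,
#' its telomere trimmed by a uniform draw from `params$trim_range`
#' (trimming never eats into the subtelomere; a draw exceeding the tract
#' truncates it to 0), virtually digested at the restriction site keeping
#' the telomeric fragment, error-injected at `params$error_rate` with the
#' substitution/insertion/deletion mix, and reported on a random strand.
#'
#' @param assembly A `"synthetic_assembly"` from [synthesize_genome_ends()].
#' @param params A [sim_params()].
#' @return A list with `reads` (named character vector of sequences) and
#'   `truth` (data.frame: read_id, assembly, chromosome, arm, haplotype,
#'   strand, true_telomere_length, pre_error_length).
#' @export
simulate_reads <- function(assembly, params = sim_params()) {
  stopifnot(inherits(assembly, "synthetic_assembly"))
  set.seed(params$seed)
  seqs <- as.character(assembly$sequences)
  arms <- assembly$arms
  reads <- character(0)
  rows <- vector("list", nrow(arms) * params$reads_per_end)
  ri <- 0L
  for (a in seq_len(nrow(arms))) {
    arm <- arms[a, ]
    contig_seq <- seqs[[arm$contig]]
    oriented <- if (arm$arm == "p") contig_seq else revcomp_string(contig_seq)
    # oriented: (CCCTAA)-form telomere at position 1
    telo_len <- arm$telomere_length
    for (r in seq_len(params$reads_per_end)) {
      ri <- ri + 1L
      trim_draw <- round(runif(1, params$trim_range[1], params$trim_range[2]))
      trimmed_telo <- max(0L, telo_len - trim_draw)
      frag <- substring(oriented, telo_len - trimmed_telo + 1L,
                        nchar(oriented))
      frag <- virtual_digest(frag, params$restriction_site,
                             params$cut_offset,
                             telomere_end = "start")$retained
      pre_error_length <- nchar(frag)
      if (params$error_rate > 0) {
        frag <- inject_errors(frag, params$error_rate, params$error_mix)
      }
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") frag <- revcomp_string(frag)
      read_id <- sprintf("%s_%s_%s_%s_%04d", arm$assembly, arm$chromosome,
                         arm$haplotype, arm$arm, r)
      reads[[read_id]] <- frag
      rows[[ri]] <- data.frame(
        read_id = read_id, assembly = arm$assembly,
        chromosome = arm$chromosome, arm = arm$arm,
        haplotype = arm$haplotype, strand = strand,
        true_telomere_length = trimmed_telo,
        pre_error_length = pre_error_length, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

#' Confusion matrix of arm assignment against simulation truth
#'
#' @param truth Truth table from [simulate_reads()].
#' @param assignments Assignment table with `read_id`, `chromosome`, `arm`
#'   (reads absent from it count as unassigned).
#' @return List with `matrix` (rows = true arms, columns = assigned arms
#'   plus `"unassigned"`), `per_arm_accuracy` (data.frame) and `overall`
#'   (fraction of reads assigned to their true arm).
#' @export
confusion_matrix <- function(truth, assignments) {
  true_arm <- paste0(truth$chromosome, truth$arm)
  idx <- match(truth$read_id, assignments$read_id)
  called <- ifelse(is.na(idx), "unassigned",
                   paste0(assignments$chromosome[idx], assignments$arm[idx]))
  arms <- sort(unique(true_arm))
  cols <- c(sort(unique(c(arms, setdiff(called, "unassigned")))), "unassigned")
  m <- table(factor(true_arm, levels = arms),
             factor(called, levels = cols))
  m <- unclass(as.matrix(m))
  diag_counts <- vapply(arms, function(a) m[a, a], numeric(1))
  acc <- data.frame(arm = arms,
                    n = rowSums(m),
                    accuracy = diag_counts / rowSums(m),
                    stringsAsFactors = FALSE)
  rownames(acc) <- NULL
  list(matrix = m, per_arm_accuracy = acc,
       overall = sum(diag_counts) / sum(m))
}

## --- internals -------------------------------------------------------------

random_dna <- function(n, avoid = NULL) {
  if (n <= 0) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (!is.null(avoid)) s <- scrub_site(s, avoid)
  s
}

# replace any occurrence of a site by rewriting its first base
scrub_site <- function(s, site) {
  repeat {
    hit <- regexpr(site, s, fixed = TRUE)
    if (hit == -1) return(s)
    old <- substr(s, hit, hit)
    repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(s, hit, hit) <- repl
  }
}

mutate_dna <- function(s, rate, avoid = NULL) {
  n <- nchar(s)
  k <- max(1L, round(n * rate))
  pos <- sample.int(n, k)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  out <- paste(chars, collapse = "")
  if (!is.null(avoid)) out <- scrub_site(out, avoid)
  out
}

# Rewrite the first `width` bases of a subtelomere `s` (which sits right
# after a tract of `motif` ending at cyclic position `phase`) so each base
# differs from the motif continuation — a wall of guaranteed mismatches
# that keeps the repeat finder from walking across the junction — while
# also keeping the junction window free of the restriction site (which
# the rewrite could otherwise recreate).
fix_junction <- function(s, telo, motif, phase, site, width = 12L) {
  k <- nchar(motif)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  w <- min(width, length(chars))
  cont_at <- function(i) {
    substr(motif, (phase + i - 1) %% k + 1L, (phase + i - 1) %% k + 1L)
  }
  for (i in seq_len(w)) {
    if (chars[i] == cont_at(i)) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), cont_at(i)), 1)
    }
  }
  telo_tail <- substr(telo, max(1L, nchar(telo) - nchar(site) + 2L),
                      nchar(telo))
  repeat {
    win_len <- min(length(chars), w + 2L * nchar(site))
    window <- paste0(telo_tail, paste(chars[seq_len(win_len)], collapse = ""))
    hit <- regexpr(site, window, fixed = TRUE)
    if (hit == -1) break
    # rewrite a site base that falls inside the subtelomere
    pos <- max(1L, as.integer(hit) - nchar(telo_tail) + 1L)
    forbidden <- unique(c(chars[pos], if (pos <= w) cont_at(pos)))
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1)
  }
  paste(chars, collapse = "")
}

sample_tract_length <- function(sampler) {
  len <- switch(sampler$dist,
    fixed = sampler$length,
    uniform = runif(1, sampler$min, sampler$max),
    lognormal = rlnorm(1, sampler$meanlog, sampler$sdlog),
    stop("unknown telomere length sampler: ", sampler$dist))
  max(0L, as.integer(round(len)))
}

# per-base errors: substitution keeps length, insertion adds a random base
# after the position, deletion removes the base
inject_errors <- function(sequence, rate, mix) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  u <- runif(n)
  err <- u < rate
  if (!any(err)) return(sequence)
  kind <- sample(c("sub", "ins", "del"), sum(err), replace = TRUE,
                 prob = mix)
  pos <- which(err)
  out <- chars
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (kind[i] == "sub") {
      out[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    } else if (kind[i] == "ins") {
      out[p] <- paste0(chars[p], sample(c("A", "C", "G", "T"), 1))
    } else {
      out[p] <- ""
    }
  }
  paste(out, collapse = "")
}
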