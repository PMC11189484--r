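# Fixture builders shared across tests. All randomness is seeded by the
# caller; sequences are built in code, never stored on disk.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a telomeric tract with uniform substitution errors at rate e
noisy_tract <- function(n_bases, motif = "TTAGGG", error = 0) {
  tract <- strsplit(substr(strrep(motif, ceiling(n_bases / nchar(motif))),
                           1, n_bases), "", fixed = TRUE)[[1]]
  if (error > 0) {
    hit <- runif(n_bases) < error
    for (p in which(hit)) {
      tract[p] <- sample(setdiff(c("A", "C", "G", "T"), tract[p]), 1)
    }
  }
  paste(tract, collapse = "")
}

revcomp <- function(s) telotape::revcomp_string(s)

# Batch of structure-filter reads with planted defects. Returns reads plus
# the planted truth (pass/fail and the specific violated criterion).
make_filter_fixture <- function(n_good = 80, n_interstitial = 10,
                                n_window = 5, n_anchor = 5, seed = 1) {
  set.seed(seed)
  reads <- character()
  truth <- list()
  add <- function(id, seq, pass, reason) {
    reads[[id]] <<- seq
    truth[[id]] <<- data.frame(read_id = id, expected_pass = pass,
                               expected_reason = reason,
                               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_good)) {
    prefix <- rand_dna(sample(0:120, 1))
    tract <- noisy_tract(sample(1500:3000, 1), "CCCTAA", error = 0.01)
    anchor <- rand_dna(sample(500:1500, 1))
    s <- paste0(prefix, tract, anchor)
    if (i %% 2 == 0) s <- revcomp(s)
    add(sprintf("good_%03d", i), s, TRUE, "")
  }
  for (i in seq_len(n_interstitial)) {
    s <- paste0(rand_dna(1000), noisy_tract(600, "TTAGGG"), rand_dna(1000))
    add(sprintf("interstitial_%02d", i), s, FALSE, "no_terminal_motif")
  }
  for (i in seq_len(n_window)) {
    s <- paste0(rand_dna(sample(260:440, 1)), noisy_tract(2000, "CCCTAA"),
                rand_dna(800))
    add(sprintf("window_%02d", i), s, FALSE,
        "motif_not_within_terminus_window")
  }
  for (i in seq_len(n_anchor)) {
    s <- paste0(noisy_tract(2000, "CCCTAA"), rand_dna(40))
    add(sprintf("anchor_%02d", i), s, FALSE,
        "insufficient_subtelomeric_anchor")
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

# small synthetic assembly + simulated reads + pangenome, for mapping tests
make_mapping_fixture <- function(n_chromosomes = 3, reads_per_end = 4,
                                 error_rate = 0, diploid = FALSE,
                                 divergence = 1 / 50, seed = 5) {
  asm <- telotape::synthesize_genome_ends(
    n_chromosomes = n_chromosomes,
    telomere_sampler = list(dist = "uniform", min = 3500, max = 7000),
    diploid = diploid, divergence = divergence, seed = seed)
  ref <- telotape::build_pangenome(list(asm), end_length = 6000,
                                   mode = "whole")
  sim <- telotape::simulate_reads(
    asm, telotape::sim_params(reads_per_end = reads_per_end,
                              error_rate = error_rate, seed = seed + 1))
  fq <- tempfile(fileext = ".fastq")
  telotape::write_fastq(sim$reads, fq)
  list(asm = asm, ref = ref, sim = sim, fastq = fq)
}
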