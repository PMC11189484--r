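test_that("pangenome end extraction emits two records per contig", {
  asm <- synthesize_genome_ends(n_chromosomes = 2, diploid = TRUE,
                                subtelomere_length = 1500,
                                telomere_sampler = list(dist = "fixed",
                                                        length = 3000),
                                seed = 3)
  ref <- suppressWarnings(
    build_pangenome(list(asm), end_length = 5000, mode = "end"))
  expect_equal(length(ref$sequences), 8L)  # 2 chrom x 2 haplotypes x 2 arms
  expect_equal(nrow(ref$regions), 8L)
  expect_setequal(unique(ref$regions$haplotype), c("maternal", "paternal"))
  expect_true(all(Biostrings::width(ref$sequences) <= 5000))
  # p records start with the telomere, annotated by the repeat finder
  p <- ref$regions[ref$regions$arm == "p", ]
  expect_true(all(p$telo_start == 0))
  expect_true(all(abs(p$telo_end - 3000) <= 6))
  expect_true(all(p$subtel_start == p$telo_end))
})

test_that("contigs shorter than the end length are kept whole with warning", {
  seqs <- Biostrings::DNAStringSet(c(chrA = paste0(
    strrep("CCCTAA", 500),
    paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = ""),
    strrep("TTAGGG", 500))))
  expect_warning(ref <- build_pangenome(list(toy = seqs),
                                        end_length = 25000, mode = "end"),
                 "overlap")
  expect_true(all(Biostrings::width(ref$sequences) == 10000))
})

test_that("reference telomere intervals match the planted tract", {
  set.seed(4)
  telo <- strrep("TTAGGG", 834)  # ~5 kb terminal tract
  sub <- paste(sample(c("A", "C", "G", "T"), 7000, replace = TRUE),
               collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("CCCTAA", 834), sub, telo)))
  ref <- build_pangenome(list(x = seqs), end_length = 6000, mode = "whole")
  q <- ref$regions[ref$regions$arm == "q", ]
  expect_equal(q$telo_end, q$record_length)
  expect_equal(q$telo_start, q$record_length - 5004, tolerance = 0.002)
  expect_equal(q$subtel_end, q$telo_start)
})

test_that("selection keeps intersecting primaries and promotes secondaries", {
  regions <- data.frame(
    record = c("A#chr7#q", "A#chr3#p"), assembly = "A",
    contig = c("chr7", "chr3"), chromosome = c("chr7", "chr3"),
    haplotype = "unphased", arm = c("q", "p"),
    telo_start = c(20000L, 0L), telo_end = c(25000L, 5000L),
    subtel_start = c(0L, 5000L), subtel_end = c(20000L, 25000L),
    record_length = 25000L, stringsAsFactors = FALSE)
  ref <- structure(list(sequences = NULL, regions = regions,
                        end_length = 25000L, mode = "end"),
                   class = "pangenome_reference")

  aln <- data.frame(
    read_id = c("r1", "r2", "r2", "r3", "r3", "r4"),
    contig = c("A#chr7#q", "elsewhere", "A#chr3#p",
               "elsewhere", "elsewhere2", "A#chr7#q"),
    start = c(15000L, 100L, 4000L, 0L, 0L, 1000L),
    end = c(22000L, 9000L, 9000L, 5000L, 5000L, 8000L),
    strand = "+", mapq = c(60L, 60L, 12L, 60L, 30L, 60L),
    rank = c("primary", "primary", "secondary", "primary", "secondary",
             "supplementary"),
    order = 1:6, stringsAsFactors = FALSE)

  asg <- select_alignments(aln, ref)
  expect_equal(asg$promotion[asg$read_id == "r1"], "primary_kept")
  expect_equal(asg$chromosome[asg$read_id == "r1"], "chr7")
  expect_equal(asg$arm[asg$read_id == "r1"], "q")
  # r2: primary misses all regions, secondary on 3p promoted
  expect_equal(asg$promotion[asg$read_id == "r2"], "secondary_promoted")
  expect_equal(asg$chromosome[asg$read_id == "r2"], "chr3")
  expect_equal(asg$mapq[asg$read_id == "r2"], 12L)
  # r3: nothing intersects; r4: supplementary never promoted
  expect_false("r3" %in% asg$read_id)
  expect_false("r4" %in% asg$read_id)
})

test_that("MAPQ tiers keep 20 at default and 12 only under cancer profile", {
  asg <- data.frame(read_id = c("a", "b", "c"), mapq = c(20L, 19L, 12L))
  expect_equal(filter_by_mapq(asg, 20L)$read_id, "a")
  expect_equal(filter_by_mapq(asg, 10L)$read_id, c("a", "b", "c"))
  cfg_default <- pipeline_config()
  cfg_cancer <- pipeline_config(profile = "cancer")
  expect_equal(cfg_default$mapq$arm_threshold, 20L)
  expect_equal(cfg_cancer$mapq$arm_threshold, 10L)
})

test_that("normalized coverage is a unit-sum fraction per arm", {
  asg <- data.frame(
    read_id = sprintf("r%02d", 1:40),
    chromosome = rep(c("chr1", "chr2"), c(30, 10)),
    arm = rep(c("p", "q"), c(30, 10)), stringsAsFactors = FALSE)
  cov <- normalized_coverage(asg)
  expect_equal(sum(cov$fraction), 1, tolerance = 1e-9)
  expect_equal(cov$fraction[cov$chromosome == "chr1"], 0.75)
  expect_equal(cov$fraction[cov$chromosome == "chr2"], 0.25)
  expect_warning(empty <- normalized_coverage(asg[0, ]), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("aligned simulated reads recover their true arms", {
  fx <- make_mapping_fixture(n_chromosomes = 3, reads_per_end = 4,
                             error_rate = 0, seed = 6)
  sam <- align_reads(fx$fastq, fx$ref)
  aln <- read_alignment_records(sam)
  asg <- filter_by_mapq(select_alignments(aln, fx$ref), 20L)
  cm <- confusion_matrix(fx$sim$truth, asg)
  expect_equal(cm$overall, 1)
  expect_true(all(cm$per_arm_accuracy$accuracy == 1))
  # assignment and length calling are independent: every assigned read's
  # call is unchanged by promotion bookkeeping
  expect_true(all(asg$promotion %in%
                    c("primary_kept", "secondary_promoted")))
})
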