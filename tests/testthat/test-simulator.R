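test_that("synthetic assemblies are deterministic and correctly shaped", {
  asm1 <- synthesize_genome_ends(n_chromosomes = 2, diploid = TRUE,
                                 telomere_sampler = list(dist = "fixed",
                                                         length = 5000),
                                 seed = 42)
  asm2 <- synthesize_genome_ends(n_chromosomes = 2, diploid = TRUE,
                                 telomere_sampler = list(dist = "fixed",
                                                         length = 5000),
                                 seed = 42)
  expect_identical(as.character(asm1$sequences),
                   as.character(asm2$sequences))
  expect_equal(nrow(asm1$arms), 8L)  # 2 chrom x 2 haplotypes x 2 ends
  expect_true(all(asm1$arms$telomere_length == 5000L))
  # contigs start with the C-strand and end with the G-strand tract
  first <- substr(as.character(asm1$sequences[[1]]), 1, 12)
  expect_equal(first, "CCCTAACCCTAA")
})

test_that("lognormal tract sampling matches the closed-form CV", {
  asm <- synthesize_genome_ends(
    n_chromosomes = 400, subtelomere_length = 30, interior_length = 12,
    telomere_sampler = list(dist = "lognormal", meanlog = log(4000),
                            sdlog = 1.0), seed = 13)
  lens <- asm$arms$telomere_length
  expect_equal(sd(lens) / mean(lens), sqrt(exp(1) - 1), tolerance = 0.15)
})

test_that("virtual digestion cuts GAT^ATC and conserves length", {
  s <- paste0(strrep("A", 10), "GATATC", strrep("C", 10))
  d <- virtual_digest(s)
  expect_equal(d$fragments, c("AAAAAAAAAAGAT", "ATCCCCCCCCCCC"))
  expect_equal(d$retained, "AAAAAAAAAAGAT")
  expect_equal(sum(nchar(d$fragments)), nchar(s))

  # no site: unchanged
  expect_equal(virtual_digest("ACGTACGT")$retained, "ACGTACGT")

  # two sites: only the terminal-most fragment is retained
  s2 <- paste0(strrep("T", 5), "GATATC", strrep("G", 5), "GATATC",
               strrep("A", 5))
  expect_equal(virtual_digest(s2, telomere_end = "start")$retained,
               "TTTTTGAT")
  expect_equal(virtual_digest(s2, telomere_end = "end")$retained,
               "ATCAAAAA")
  expect_equal(sum(nchar(virtual_digest(s2)$fragments)), nchar(s2))
})

test_that("read counts, trimming truth, and seeded determinism hold", {
  asm <- synthesize_genome_ends(n_chromosomes = 3,
                                telomere_sampler = list(dist = "fixed",
                                                        length = 4000),
                                seed = 2)
  p <- sim_params(reads_per_end = 30L, error_rate = 0, seed = 5)
  sim <- simulate_reads(asm, p)
  expect_equal(length(sim$reads), 6L * 30L)
  expect_true(all(sim$truth$true_telomere_length >= 1000L))
  expect_true(all(sim$truth$true_telomere_length <= 4000L))
  sim2 <- simulate_reads(asm, p)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)

  # a trim range exceeding the tract truncates the telomere to zero
  deep <- simulate_reads(asm, sim_params(trim_range = c(5000, 5000),
                                         reads_per_end = 1L,
                                         error_rate = 0, seed = 5))
  expect_true(all(deep$truth$true_telomere_length == 0L))
  expect_equal(length(deep$reads), 6L)
})

test_that("injected error rates match their nominal components", {
  base <- strrep("A", 100000)
  set.seed(31)
  subs <- telotape:::inject_errors(base, 0.02, c(1, 0, 0))
  sub_rate <- sum(strsplit(subs, "", fixed = TRUE)[[1]] != "A") / 100000
  expect_equal(sub_rate, 0.02, tolerance = 0.1)

  set.seed(32)
  ins <- telotape:::inject_errors(base, 0.02, c(0, 1, 0))
  expect_equal((nchar(ins) - 100000) / 100000, 0.02, tolerance = 0.1)

  set.seed(33)
  del <- telotape:::inject_errors(base, 0.02, c(0, 0, 1))
  expect_equal((100000 - nchar(del)) / 100000, 0.02, tolerance = 0.1)
})

test_that("confusion matrices expose planted subtelomere homology", {
  truth <- data.frame(read_id = sprintf("r%d", 1:6),
                      chromosome = rep(c("chr1", "chr2", "chr3"), each = 2),
                      arm = "p", stringsAsFactors = FALSE)
  # perfect assignment: identity matrix
  perfect <- data.frame(read_id = truth$read_id,
                        chromosome = truth$chromosome, arm = truth$arm,
                        stringsAsFactors = FALSE)
  cm <- confusion_matrix(truth, perfect)
  expect_equal(cm$overall, 1)
  expect_true(all(diag(cm$matrix[, rownames(cm$matrix)]) == 2))

  # all unassigned: the mass moves to the unassigned column
  cm0 <- confusion_matrix(truth, perfect[0, ])
  expect_equal(cm0$overall, 0)
  expect_true(all(cm0$matrix[, "unassigned"] == 2))

  # homologous pair: off-diagonal mass confined to the planted pair
  swapped <- perfect
  swapped$chromosome[swapped$chromosome == "chr2"] <- "chr1"
  cmh <- confusion_matrix(truth, swapped)
  expect_equal(cmh$matrix["chr2p", "chr1p"], 2)
  expect_equal(cmh$per_arm_accuracy$accuracy[
    cmh$per_arm_accuracy$arm == "chr3p"], 1)
})
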