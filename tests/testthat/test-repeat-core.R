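test_that("perfect and complement tracts are found with exact boundaries", {
  spec <- motif_spec()

  seg <- find_repeat_segments(strrep("TTAGGG", 20), spec)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 0L)
  expect_equal(seg$end, 120L)
  expect_equal(seg$form, "G")
  expect_equal(seg$identity, 1)

  # C-strand tract opening the read; flank chosen not to extend the repeat
  set.seed(3)
  flank <- rand_dna(300)
  while (substr(flank, 1, 1) == "C") flank <- rand_dna(300)
  seg2 <- find_repeat_segments(paste0(strrep("CCCTAA", 10), flank), spec)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$start, 0L)
  expect_equal(seg2$end, 60L)
  expect_equal(seg2$form, "C")
})

test_that("sequences without telomeric repeats yield no segments", {
  set.seed(11)
  expect_equal(nrow(find_repeat_segments(rand_dna(500))), 0L)
  expect_equal(nrow(find_repeat_segments("")), 0L)
})

test_that("non-DNA characters are rejected, N counts as mismatch", {
  expect_error(find_repeat_segments("ACGTX"), "A/C/G/T/N")
  # one N inside a perfect tract lowers identity but keeps the segment
  tract <- strrep("TTAGGG", 20)
  substr(tract, 60, 60) <- "N"
  seg <- find_repeat_segments(tract)
  expect_equal(nrow(seg), 1L)
  expect_lt(seg$identity, 1)
  expect_gt(seg$identity, 0.98)
})

test_that("noisy tract segments match the exhaustive wraparound DP oracle", {
  set.seed(21)
  spec <- motif_spec()
  tract <- noisy_tract(600, "TTAGGG", error = 0.02)
  seg <- find_repeat_segments(tract, spec)
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$end - seg$start, 0.95 * 600)
  expect_gt(seg$identity, 0.95)
  expect_identical(seg, oracle_find_segments(tract, spec))
})

test_that("randomized reads reproduce the oracle exactly", {
  set.seed(77)
  spec <- motif_spec()
  for (i in 1:25) {
    kind <- i %% 3
    s <- if (kind == 0) rand_dna(sample(200:1000, 1)) else {
      paste0(rand_dna(sample(0:150, 1)),
             noisy_tract(sample(300:900, 1),
                         sample(c("TTAGGG", "CCCTAA"), 1),
                         error = if (kind == 1) 0 else 0.02),
             rand_dna(sample(0:300, 1)))
    }
    expect_identical(find_repeat_segments(s, spec),
                     oracle_find_segments(s, spec))
  }
})

test_that("reverse-complementing a read mirrors segments and swaps forms", {
  set.seed(5)
  spec <- motif_spec()
  s <- paste0(rand_dna(120), noisy_tract(700, "CCCTAA", 0.02),
              rand_dna(500), noisy_tract(300, "TTAGGG", 0.01),
              rand_dna(80))
  fwd <- find_repeat_segments(s, spec)
  bwd <- find_repeat_segments(revcomp(s), spec)
  expect_equal(nrow(fwd), nrow(bwd))
  n <- nchar(s)
  mirrored <- data.frame(start = n - rev(bwd$end), end = n - rev(bwd$start),
                         form = ifelse(rev(bwd$form) == "G", "C", "G"),
                         identity = rev(bwd$identity),
                         score = rev(bwd$score), stringsAsFactors = FALSE)
  expect_equal(fwd, mirrored, ignore_attr = TRUE)
})

test_that("lowering min_identity never removes an emitted segment", {
  set.seed(31)
  s <- paste0(noisy_tract(400, "TTAGGG", 0.05), rand_dna(300),
              noisy_tract(200, "TTAGGG", 0.12))
  strict <- find_repeat_segments(s, motif_spec(min_identity = 0.9))
  loose <- find_repeat_segments(s, motif_spec(min_identity = 0.8))
  for (i in seq_len(nrow(strict))) {
    expect_true(any(loose$start == strict$start[i] &
                      loose$end == strict$end[i]))
  }
  expect_gte(nrow(loose), nrow(strict))
})

test_that("tract recall exceeds 0.95 at up to 5% error", {
  set.seed(41)
  recalls <- replicate(20, {
    tract_len <- sample(500:2000, 1)
    s <- paste0(rand_dna(100), noisy_tract(tract_len, "TTAGGG", 0.05),
                rand_dna(100))
    seg <- find_repeat_segments(s)
    covered <- sum(pmin(seg$end, 100 + tract_len) - pmax(seg$start, 100))
    covered / tract_len
  })
  expect_gt(mean(recalls), 0.95)
})

test_that("segment_gap measures inter-segment distance and rejects overlap", {
  a <- data.frame(start = 0L, end = 3000L)
  b <- data.frame(start = 3100L, end = 5000L)
  expect_equal(segment_gap(a, b), 100L)
  expect_equal(segment_gap(data.frame(start = 0L, end = 100L),
                           data.frame(start = 100L, end = 200L)), 0L)
  expect_equal(segment_gap(data.frame(start = 0L, end = 100L),
                           data.frame(start = 350L, end = 500L)), 250L)
  expect_error(segment_gap(b, a), "overlap")
})
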