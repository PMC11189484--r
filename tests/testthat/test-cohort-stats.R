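test_that("length summaries compute the standard moments and bins", {
  s <- summarize_lengths(c(1000, 2000, 3000))
  expect_equal(s$mean, 2000)
  expect_equal(s$median, 2000)
  expect_equal(s$sd, 1000)
  expect_equal(s$cv, 0.5)
  expect_equal(s$fraction_below_1kb, 0)   # strict: 1000 is not below 1 kb
  expect_equal(s$fraction_above_10kb, 0)

  flat <- summarize_lengths(rep(4000, 10))
  expect_equal(flat$sd, 0)
  expect_equal(flat$cv, 0)

  b <- summarize_lengths(c(999, 1000, 5000, 10000, 10001))
  expect_equal(b$fraction_below_1kb, 0.2)
  expect_equal(b$fraction_above_10kb, 0.2)

  expect_error(summarize_lengths(numeric(0)), "at least one")
})

test_that("summaries are permutation-invariant and scale-equivariant", {
  set.seed(17)
  x <- rlnorm(500, log(5000), 0.5)
  a <- summarize_lengths(x)
  b <- summarize_lengths(sample(x))
  expect_equal(a, b)
  k <- 3.7
  sc <- summarize_lengths(k * x)
  expect_equal(sc$mean, k * a$mean)
  expect_equal(sc$sd, k * a$sd)
  expect_equal(sc$median, k * a$median)
  expect_equal(sc$cv, a$cv)
})

test_that("lognormal CV matches its closed form on large samples", {
  set.seed(18)
  x <- rlnorm(1e6, log(4000), 0.9)
  expect_equal(summarize_lengths(x)$cv, sqrt(exp(0.81) - 1),
               tolerance = 0.02)
})

test_that("shortening regression recovers exact and noisy slopes", {
  pds <- seq(60, 100, 5)
  exact <- fit_shortening(pds, 7000 - 39 * pds)
  expect_equal(exact$slope, -39, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)
  expect_true(exact$ci_lo <= exact$slope && exact$slope <= exact$ci_hi)
  expect_error(fit_shortening(c(1, 2), c(5, 6)), "3 points")

  set.seed(19)
  slopes <- replicate(200, {
    fit_shortening(pds, 7000 - 39 * pds + rnorm(9, 0, 100))$slope
  })
  expect_equal(mean(slopes), -39, tolerance = 3 / 39)
})

test_that("TMM calls follow the CV thresholds with an indeterminate band", {
  mk <- function(cv, n = 500) data.frame(n_reads = n, cv = cv)
  expect_equal(classify_tmm(mk(0.9)), "ALT-like")
  expect_equal(classify_tmm(mk(0.3)), "TERT-like")
  expect_equal(classify_tmm(mk(0.65)), "indeterminate")
  expect_equal(classify_tmm(mk(0.8)), "indeterminate")   # boundary
  expect_equal(classify_tmm(mk(0.55)), "indeterminate")  # boundary
  expect_equal(classify_tmm(mk(0.9, n = 50)), "indeterminate")
})

test_that("subsampling dispersion follows the square-root law", {
  set.seed(20)
  pop <- rlnorm(8000, log(5000), 0.4)
  sigma <- sd(pop)
  for (n in c(32, 128, 512)) {
    r <- subsample_model(pop, n, n_reps = 500, seed = 21)
    expect_equal(r$sd_of_means, sigma / sqrt(n), tolerance = 0.15)
  }
  # full-population subsample has no dispersion; same seed reproduces
  expect_equal(subsample_model(pop, length(pop), n_reps = 5,
                               seed = 1)$sd_of_means, 0)
  expect_identical(subsample_model(pop, 64, seed = 9),
                   subsample_model(pop, 64, seed = 9))
  expect_error(subsample_model(pop, length(pop) + 1), "exceeds")
})

test_that("arm ranking standardizes within samples and is equivariant", {
  arms <- expand.grid(sample = c("s1", "s2"),
                      arm = c("1p", "1q", "2p", "2q"),
                      stringsAsFactors = FALSE)
  arms$mean <- 5000
  flat <- rank_arms(arms)
  expect_true(all(flat$z$z == 0))

  arms$mean[arms$arm == "2q"] <- 9000
  top <- rank_arms(arms)
  expect_equal(top$ranking$arm[1], "2q")
  expect_equal(top$ranking$rank[top$ranking$arm == "2q"], 1L)

  # permuting arm labels permutes ranks identically
  perm <- arms
  perm$arm <- c("1p" = "2p", "1q" = "1q", "2p" = "1p",
                "2q" = "2q")[perm$arm]
  r1 <- rank_arms(arms)$ranking
  r2 <- rank_arms(perm)$ranking
  expect_equal(r2$rank[r2$arm == "2q"], r1$rank[r1$arm == "2q"])
  expect_equal(r2$mean_z[r2$arm == "1p"], r1$mean_z[r1$arm == "2p"])
})

test_that("distribution comparisons use two-sided t with Bonferroni", {
  x <- rep(c(4000, 5000), 10)
  same <- compare_distributions(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_adjusted, 1)

  set.seed(22)
  a <- rnorm(500, 5000, 100)
  b <- rnorm(500, 4000, 100)
  diff <- compare_distributions(a, b, n_comparisons = 10)
  expect_lt(diff$p_adjusted, 1e-10)
  raw <- compare_distributions(a, b, n_comparisons = 1)
  expect_equal(raw$p_adjusted, raw$p_value)
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
})

test_that("arm concordance filters by coverage and recovers planted fits", {
  arms <- sprintf("arm%02d", 1:10)
  a <- data.frame(arm = arms, mean = seq(3000, 12000, 1000), n_reads = 30)
  b <- a
  expect_equal(arm_length_concordance(a, b)$slope, 1, tolerance = 1e-10)
  expect_equal(arm_length_concordance(a, b)$intercept, 0,
               tolerance = 1e-6)

  b$mean <- 0.5 * a$mean + 5000
  fit <- arm_length_concordance(a, b)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 5000, tolerance = 1e-6)

  a$n_reads[1:3] <- 19L
  expect_equal(arm_length_concordance(a, b)$n_arms, 7L)
  a$n_reads <- 19L
  expect_error(arm_length_concordance(a, b), "fewer than 3")
})
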