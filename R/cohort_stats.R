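#' Summarize a telomere length distribution
#'
#' Standard per-sample (or per-arm, per-allele) summary of per-read
#' telomere lengths: mean, median, sample standard deviation (n-1
#' denominator), coefficient of variation, interquartile range, and the
#' fractions of reads strictly below 1 kb and strictly above 10 kb.
#'
#' @param lengths Numeric vector of per-read telomere lengths in bp
#'   (non-empty).
#' @param short_bp,long_bp Bin edges for the short/long fractions
#'   (strict inequalities). Defaults 1000 and 10000.
#' @return A one-row data.frame: `n_reads`, `mean`, `median`, `sd`, `cv`,
#'   `iqr`, `fraction_below_1kb`, `fraction_above_10kb`, `min`, `max`.
#' @export
#' @examples
#' summarize_lengths(c(1000, 2000, 3000))
summarize_lengths <- function(lengths, short_bp = 1000, long_bp = 10000) {
  if (length(lengths) < 1L) stop("summarize_lengths needs at least one length")
  m <- mean(lengths)
  s <- if (length(lengths) > 1L) sd(lengths) else 0
  data.frame(n_reads = length(lengths), mean = m, median = median(lengths),
             sd = s, cv = if (m > 0) s / m else NA_real_,
             iqr = IQR(lengths),
             fraction_below_1kb = mean(lengths < short_bp),
             fraction_above_10kb = mean(lengths > long_bp),
             min = min(lengths), max = max(lengths))
}

#' Fit a telomere shortening rate
#'
#' Ordinary least squares of mean telomere length against population
#' doublings (or donor age). Shortening appears as a negative slope in
#' bp per unit of x.
#'
#' @param x Population doublings or ages (at least 3 distinct values).
#' @param y Mean telomere lengths (bp), same length as `x`.
#' @return A one-row data.frame: `slope`, `intercept`, `ci_lo`, `ci_hi`
#'   (95% CI for the slope), `r_squared`, `n_points`.
#' @export
#' @examples
#' fit_shortening(seq(60, 100, 5), 7000 - 39 * seq(60, 100, 5))
fit_shortening <- function(x, y) {
  if (length(x) < 3L || length(unique(x)) < 3L) {
    stop("fit_shortening needs at least 3 points with distinct x")
  }
  stopifnot(length(x) == length(y))
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, "x", level = 0.95))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  data.frame(slope = unname(coef(fit)["x"]),
             intercept = unname(coef(fit)["(Intercept)"]),
             ci_lo = ci[1], ci_hi = ci[2],
             r_squared = r2,
             n_points = length(x))
}

#' Classify telomere maintenance mechanism from distribution dispersion
#'
#' ALT-positive cells show highly heterogeneous telomere lengths while
#' telomerase-positive cells are tightly distributed; the coefficient of
#' variation of the per-read length distribution separates the two.
#' CV above `alt_cv` calls ALT-like, CV below `tert_cv` calls TERT-like,
#' and the band in between is indeterminate.
#'
#' @param summary A one-row summary from [summarize_lengths()] (or
#'   anything with `cv` and `n_reads`).
#' @param alt_cv ALT threshold. Default 0.8.
#' @param tert_cv Telomerase threshold. Default 0.55.
#' @param min_reads Minimum reads for a confident call. Default 100.
#' @return `"ALT-like"`, `"TERT-like"`, or `"indeterminate"`.
#' @export
classify_tmm <- function(summary, alt_cv = 0.8, tert_cv = 0.55,
                         min_reads = 100L) {
  stopifnot(tert_cv <= alt_cv)
  if (summary$n_reads < min_reads) return("indeterminate")
  cv <- summary$cv
  if (is.na(cv)) return("indeterminate")
  if (cv > alt_cv) "ALT-like" else if (cv < tert_cv) "TERT-like" else "indeterminate"
}

#' Subsampling precision model
#'
#' Estimates how the precision of the mean telomere length depends on
#' read count: draws `n_reps` without-replacement subsamples of `n_reads`
#' reads from the bulk distribution and reports the dispersion of the
#' subsample means.
#'
#' @param lengths Bulk per-read telomere lengths.
#' @param n_reads Subsample size (at most `length(lengths)`).
#' @param n_reps Number of subsamples. Default 10.
#' @param seed Integer seed.
#' @return A one-row data.frame: `n_reads`, `n_reps`, `mean_of_means`,
#'   `sd_of_means`.
#' @export
subsample_model <- function(lengths, n_reads, n_reps = 10L, seed = 1L) {
  if (n_reads > length(lengths)) {
    stop("n_reads exceeds the population size")
  }
  set.seed(seed)
  means <- vapply(seq_len(n_reps), function(i) {
    mean(sample(lengths, n_reads, replace = FALSE))
  }, numeric(1))
  data.frame(n_reads = as.integer(n_reads), n_reps = as.integer(n_reps),
             mean_of_means = mean(means),
             sd_of_means = if (n_reps > 1L) sd(means) else 0)
}

#' Rank chromosome arms by relative telomere length
#'
#' Within each sample, the z-score of an arm is its mean telomere length
#' standardized against the distribution of arm means in that sample;
#' arms are then ranked across samples by their average z-score
#' (rank 1 = longest relative telomeres).
#'
#' @param arm_means data.frame with columns `sample`, `arm`, `mean`
#'   (mean telomere length of the arm in that sample).
#' @return List with `z` (the input plus a `z` column) and `ranking`
#'   (data.frame `arm`, `mean_z`, `rank`).
#' @export
rank_arms <- function(arm_means) {
  stopifnot(all(c("sample", "arm", "mean") %in% names(arm_means)))
  sp <- split(arm_means, arm_means$sample)
  z <- lapply(sp, function(d) {
    if (nrow(d) < 2L) stop("rank_arms needs at least 2 arms per sample")
    mu <- mean(d$mean); s <- sd(d$mean)
    d$z <- if (s > 0) (d$mean - mu) / s else 0
    d
  })
  z <- do.call(rbind, z)
  rownames(z) <- NULL
  mz <- tapply(z$z, z$arm, mean)
  ranking <- data.frame(arm = names(mz), mean_z = as.numeric(mz),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_z), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(z = z, ranking = ranking)
}

#' Compare two telomere length distributions
#'
#' Two-sided independent t-test with Bonferroni correction across
#' `n_comparisons` tests. Welch's variant is the default; set
#' `var_equal = TRUE` for the pooled-variance test.
#'
#' @param a,b Numeric length vectors (each n >= 2).
#' @param n_comparisons Number of tests in the family. Default 1.
#' @param var_equal Assume equal variances. Default FALSE (Welch).
#' @return A one-row data.frame: `t_statistic`, `p_value`, `p_adjusted`
#'   (`min(1, p * n_comparisons)`), `df`.
#' @export
compare_distributions <- function(a, b, n_comparisons = 1L,
                                  var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 observations")
  }
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate identical constant samples: no evidence of difference
    return(data.frame(t_statistic = 0, p_value = 1, p_adjusted = 1,
                      df = length(a) + length(b) - 2))
  }
  tt <- t.test(a, b, alternative = "two.sided", var.equal = var_equal)
  data.frame(t_statistic = unname(tt$statistic),
             p_value = tt$p.value,
             p_adjusted = min(1, tt$p.value * n_comparisons),
             df = unname(tt$parameter))
}

#' Arm-level telomere length concordance between two samples
#'
#' OLS regression of per-arm mean telomere lengths of sample B on sample
#' A, restricted to arms with at least `min_coverage` reads in both.
#' In a fibroblast-versus-iPSC comparison, a slope below 1 with a
#' positive intercept indicates preferential elongation of short
#' telomeres.
#'
#' @param a,b data.frames with columns `arm`, `mean`, `n_reads` for the
#'   two samples.
#' @param min_coverage Minimum reads per arm in both samples. Default 20.
#' @return A one-row data.frame: `slope`, `intercept`, `r_squared`,
#'   `n_arms`.
#' @export
arm_length_concordance <- function(a, b, min_coverage = 20L) {
  a <- a[a$n_reads >= min_coverage, , drop = FALSE]
  b <- b[b$n_reads >= min_coverage, , drop = FALSE]
  shared <- intersect(a$arm, b$arm)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared arms after the coverage filter")
  }
  x <- a$mean[match(shared, a$arm)]
  y <- b$mean[match(shared, b$arm)]
  fit <- lm(y ~ x)
  data.frame(slope = unname(coef(fit)["x"]),
             intercept = unname(coef(fit)["(Intercept)"]),
             r_squared = suppressWarnings(summary(fit)$r.squared),
             n_arms = length(shared))
}

#' Per-arm length summaries from calls and assignments
#'
#' Joins per-read telomere calls to arm assignments and summarizes each
#' chromosome arm.
#'
#' @param calls Telomere call table (with `read_id`, `telomere_length`).
#' @param assignments Arm assignment table (MAPQ-filtered as desired).
#' @return data.frame with `chromosome`, `arm` and the columns of
#'   [summarize_lengths()].
#' @export
summarize_arms <- function(calls, assignments) {
  idx <- match(assignments$read_id, calls$read_id)
  keep <- !is.na(idx)
  d <- data.frame(chromosome = assignments$chromosome[keep],
                  arm = assignments$arm[keep],
                  length = calls$telomere_length[idx[keep]],
                  stringsAsFactors = FALSE)
  sp <- split(d, paste0(d$chromosome, "#", d$arm))
  out <- lapply(sp, function(g) {
    cbind(data.frame(chromosome = g$chromosome[1], arm = g$arm[1],
                     stringsAsFactors = FALSE),
          summarize_lengths(g$length))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
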