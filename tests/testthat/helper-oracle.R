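# Independent brute-force oracle for the repeat finder: a naive, pure-R
# wraparound local DP against the cyclic motif with the same mathematical
# definition as the package (scores, sweep-to-fixpoint row updates,
# best-cell tie-breaks, traceback preference diagonal > up > left,
# masked iterative extraction, greedy cross-form overlap resolution).
# Written from the definition, not from the package internals.

oracle_dp_candidates <- function(sequence, motif, match, mismatch, gap,
                                 stop_score) {
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  n <- length(x)
  k <- length(m)
  sub_score <- function(a, b) {
    if (a == "N" || b == "N") mismatch else if (a == b) match else mismatch
  }
  H <- matrix(0L, nrow = n + 1, ncol = k)
  masked <- rep(FALSE, n)
  jm1 <- c(k, seq_len(k - 1))

  compute_rows <- function(from_row) {
    for (i in from_row:(n + 1)) {
      if (i == 1) next
      pos <- i - 1
      if (masked[pos]) { H[i, ] <<- 0L; next }
      row <- rep(0L, k)
      repeat_count <- 0
      repeat {
        changed <- FALSE
        repeat_count <- repeat_count + 1
        for (j in seq_len(k)) {
          d <- H[i - 1, jm1[j]] + sub_score(x[pos], m[j])
          u <- H[i - 1, j] + gap
          l <- row[jm1[j]] + gap
          v <- max(0L, d, u, l)
          if (v > row[j]) { row[j] <- v; changed <- TRUE }
        }
        if (!changed || repeat_count >= k + 2) break
      }
      H[i, ] <<- row
    }
  }

  compute_rows(1)
  out <- list()
  repeat {
    best <- 0L; bi <- -1L; bj <- -1L
    for (i in 2:(n + 1)) {
      for (j in seq_len(k)) {
        if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
      }
    }
    if (bi < 0 || best < stop_score) break
    i <- bi; j <- bj
    matches <- 0L; columns <- 0L; min_pos <- bi - 1L
    while (H[i, j] > 0L) {
      d <- H[i - 1, jm1[j]] + sub_score(x[i - 1], m[j])
      if (H[i, j] == d) {
        columns <- columns + 1L
        if (x[i - 1] != "N" && x[i - 1] == m[j]) matches <- matches + 1L
        min_pos <- i - 1L
        i <- i - 1L; j <- jm1[j]
      } else if (H[i, j] == H[i - 1, j] + gap) {
        columns <- columns + 1L
        min_pos <- i - 1L
        i <- i - 1L
      } else {
        columns <- columns + 1L
        j <- jm1[j]
      }
    }
    start0 <- min_pos - 1L
    end0 <- bi - 1L
    out[[length(out) + 1L]] <- data.frame(
      start = start0, end = end0, score = best,
      identity = matches / columns)
    masked[(start0 + 1L):end0] <- TRUE
    compute_rows(start0 + 1L)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      score = integer(), identity = numeric()))
  }
  do.call(rbind, out)
}

# same candidate-pool resolution as the definition: score-descending
# greedy, ties preferring the strand form expected at the nearer read
# terminus, then smaller start, then form; filter afterwards
oracle_find_segments <- function(sequence, spec = motif_spec()) {
  stop_score <- max(1L, as.integer(ceiling(
    spec$min_segment_length *
      (spec$min_identity * spec$match +
         (1 - spec$min_identity) * spec$mismatch))))
  n <- nchar(sequence)
  pool <- list()
  for (form in c("G", "C")) {
    motif <- if (form == "G") spec$canonical_motif else spec$complement_motif
    cand <- oracle_dp_candidates(sequence, motif, spec$match,
                                 spec$mismatch, spec$gap, stop_score)
    if (nrow(cand)) { cand$form <- form; pool[[form]] <- cand }
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool) || nrow(pool) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      form = character(), identity = numeric(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  mid <- (pool$start + pool$end) / 2
  pref <- as.integer(pool$form == ifelse(mid < n / 2, "C", "G"))
  pool <- pool[order(-pool$score, -pref, pool$start, pool$form), ,
               drop = FALSE]
  keep <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    keep[i] <- !any(keep & pool$start < pool$end[i] & pool$end > pool$start[i])
  }
  res <- pool[keep, , drop = FALSE]
  res <- res[(res$end - res$start) >= spec$min_segment_length &
               res$identity >= spec$min_identity, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  data.frame(start = as.integer(res$start), end = as.integer(res$end),
             form = res$form, identity = res$identity,
             score = as.integer(res$score), stringsAsFactors = FALSE)
}
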