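# Independent oracles used across the test files.

# Needleman-Wunsch against a long finite unrolling of the unit, free end in
# the pattern. Independent of the package's cyclic DP: the pattern side is
# an explicit string, and the recurrence is the textbook global-alignment
# matrix. Unrolling length 2n + 2p is enough: consuming an extra pattern
# character costs an indel, so optimal alignments never use more than
# n + score-budget/indel pattern characters.
oracle_score_tract <- function(seq, unit, match = 2, mismatch = 7,
                               indel = 7) {
  s <- strsplit(toupper(seq), "")[[1L]]
  u <- strsplit(toupper(unit), "")[[1L]]
  n <- length(s)
  if (n == 0L) return(0)
  reps <- ceiling((2 * n) / length(u)) + 2L
  p <- rep(u, reps)
  m <- length(p)
  D <- matrix(-Inf, n + 1L, m + 1L)
  D[1L, ] <- -(0:m) * indel   # leading pattern deletions
  for (i in seq_len(n)) {
    D[i + 1L, 1L] <- D[i, 1L] - indel
    sub <- ifelse(s[i] == p & s[i] %in% c("A", "C", "G", "T"),
                  match, -mismatch)
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- max(D[i, j] + sub[j],
                               D[i, j + 1L] - indel,
                               D[i + 1L, j] - indel)
    }
  }
  max(D[n + 1L, ])  # free pattern end
}

oracle_min_rotation <- function(unit) {
  ch <- strsplit(unit, "")[[1L]]
  k <- length(ch)
  min(vapply(seq_len(k), function(i)
    paste(ch[c(seq(i, k), seq_len(i - 1L))], collapse = ""), ""))
}

# Exhaustive candidate enumeration + greedy maximal non-overlapping
# selection, replicating the declared tie-break order. Scores come from
# score_tract (whose semantics are verified separately against
# oracle_score_tract); what this oracle exercises exhaustively is
# detection: every (substring, period) candidate is considered, with no
# seed-window shortcut.
oracle_scan <- function(seq, params = tnrscan::scan_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  cand <- list()
  for (p in seq_len(params$max_period)) {
    for (s0 in 0:(n - p)) {
      unit <- substr(seq, s0 + 1L, s0 + p)
      if (grepl("[^ACGT]", unit)) next
      for (e0 in (s0 + 1L):n) {
        if (!ch[e0] %in% c("A", "C", "G", "T")) next
        sc <- tnrscan::score_tract(substr(seq, s0 + 1L, e0), unit, params)
        if (sc$score >= params$min_score)
          cand[[length(cand) + 1L]] <-
            data.frame(start = s0, end = e0, period = p, score = sc$score,
                       unit = unit, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), score = integer(0)))
  cand <- do.call(rbind, cand)
  cand$cu <- vapply(cand$unit, oracle_min_rotation, "")
  cand <- cand[order(-cand$score, -(cand$end - cand$start), cand$start,
                     cand$cu), ]
  sel <- list()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    sel[[length(sel) + 1L]] <- top
    cand <- cand[!(cand$start < top$end & cand$end > top$start), ,
                 drop = FALSE]
  }
  out <- do.call(rbind, sel)
  out <- out[order(out$start), c("start", "end", "period", "score")]
  rownames(out) <- NULL
  out
}

# Exhaustive enumeration with an incremental pure-R cyclic DP (one row per
# candidate end), then the same greedy selection as oracle_scan. Used where
# per-substring rescoring is too slow; the scoring recurrence itself is
# checked against the unrolled NW oracle elsewhere.
oracle_scan_fast <- function(seq, params = tnrscan::scan_params()) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  acgt <- c("A", "C", "G", "T")
  match_w <- params$match; mis <- params$mismatch; ind <- params$indel
  cand <- list()
  for (p in seq_len(params$max_period)) {
    for (s0 in 0:(n - p)) {
      u <- ch[(s0 + 1L):(s0 + p)]
      if (!all(u %in% acgt)) next
      D <- c(0, if (p > 1L) -(1:(p - 1L)) * ind)
      for (i in (s0 + 1L):n) {
        nD <- rep(-1e9, p)
        for (j in seq_len(p)) {
          jn <- if (j == p) 1L else j + 1L
          diag <- D[j] + (if (ch[i] == u[j]) match_w else -mis)
          if (diag > nD[jn]) nD[jn] <- diag
          insv <- D[j] - ind
          if (insv > nD[j]) nD[j] <- insv
        }
        if (p > 1L) for (pass in 1:2) for (j in seq_len(p)) {
          jn <- if (j == p) 1L else j + 1L
          del <- nD[j] - ind
          if (del > nD[jn]) nD[jn] <- del
        }
        D <- nD
        best <- max(D)
        if (best + 2 * match_w * (n - i) < params$min_score) break
        if (best >= params$min_score && ch[i] %in% acgt)
          cand[[length(cand) + 1L]] <- c(s0, i, p, best)
      }
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), score = integer(0)))
  m <- do.call(rbind, cand)
  d <- data.frame(start = m[, 1L], end = m[, 2L], period = m[, 3L],
                  score = m[, 4L])
  d$unit <- substr(rep(seq, nrow(d)), d$start + 1L, d$start + d$period)
  d$cu <- vapply(d$unit, oracle_min_rotation, "")
  d <- d[order(-d$score, -(d$end - d$start), d$start, d$cu), ]
  sel <- list()
  while (nrow(d) > 0L) {
    top <- d[1L, ]
    sel[[length(sel) + 1L]] <- top
    d <- d[!(d$start < top$end & d$end > top$start), , drop = FALSE]
  }
  out <- do.call(rbind, sel)
  out <- out[order(out$start), c("start", "end", "period", "score")]
  rownames(out) <- NULL
  out
}

# spacer with no self-similarity at lags 1-3 (period 4 > max period)
neutral_spacer <- function(n_units) strrep("ACGT", n_units)

# embed an exact-length prefix of a repeated unit between neutral spacers,
# with two phase-breaking bases on each side so the planted boundaries are
# score-maximal
embed_pure <- function(unit, len, pad_units = 15L) {
  u <- strsplit(unit, "")[[1L]]
  p <- length(u)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
  exp_at <- function(off) u[(off %% p) + 1L]
  tract <- substr(strrep(unit, ceiling(len / p)), 1L, len)
  left <- paste0(other(exp_at(-2L)), other(exp_at(-1L)))
  right <- paste0(other(exp_at(len)), other(exp_at(len + 1L)))
  list(seq = paste0(neutral_spacer(pad_units), left, tract, right,
                    neutral_spacer(pad_units)),
       start = 4L * pad_units + 2L,
       end = 4L * pad_units + 2L + len)
}

# plant pure tracts into a random background, with the repeat phase broken
# two bases deep at both boundaries so planted loci are score-maximal
plant_tracts <- function(len, plants, seed) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  truth <- list()
  for (pl in plants) {
    u <- strsplit(pl$unit, "")[[1L]]
    p <- length(u)
    tl <- p * pl$copies
    s0 <- pl$at
    bases[(s0 + 1L):(s0 + tl)] <- rep(u, pl$copies)
    fixpos <- function(idx, forbidden) {
      if (idx >= 1L && idx <= len && bases[idx] == forbidden)
        bases[idx] <<- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
    }
    # expected continuation bases at offsets -1, -2, tl, tl+1 (0-based)
    exp_at <- function(off) u[(off %% p) + 1L]
    fixpos(s0, exp_at(-1L)); fixpos(s0 - 1L, exp_at(-2L))
    fixpos(s0 + tl + 1L, exp_at(tl)); fixpos(s0 + tl + 2L, exp_at(tl + 1L))
    truth[[length(truth) + 1L]] <- data.frame(start = s0, end = s0 + tl,
                                              unit = pl$unit,
                                              stringsAsFactors = FALSE)
  }
  list(seq = paste(bases, collapse = ""), truth = do.call(rbind, truth))
}
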