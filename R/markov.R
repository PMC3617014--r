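#' Fit an order-2 Markov nucleotide background
#'
#' Tallies every overlapping (dinucleotide context, next base) occurrence
#' across the input sequences (no wrap across sequence boundaries; windows
#' containing N are skipped) and forms conditional probabilities
#' \eqn{P(c \mid ab) = (n_{abc} + q) / (n_{ab\cdot} + 4q)} with pseudocount
#' \eqn{q}. The empirical dinucleotide distribution is retained alongside,
#' so expected trinucleotide frequencies can be derived.
#'
#' @param seqs DNA sequences (character vector or \code{DNAStringSet}).
#' @param pseudocount non-negative pseudocount added per (context, base) cell.
#' @return An object of class \code{"markov2"}: \code{context_counts}
#'   (16 x 4 matrix), \code{cond_prob} (16 x 4, rows sum to 1),
#'   \code{dinuc_freq} (length 16, sums to 1), \code{pseudocount}.
#' @examples
#' m <- fit_markov2("ACGTACGT")
#' m$cond_prob["AC", "G"]  # 1
#' @export
fit_markov2 <- function(seqs, pseudocount = 0) {
  seqs <- as_seq_char(seqs)
  if (sum(nchar(seqs)) < 3L) stop("need at least 3 nt in total")
  dss <- Biostrings::DNAStringSet(seqs)
  tri <- colSums(Biostrings::trinucleotideFrequency(dss))
  di <- colSums(Biostrings::dinucleotideFrequency(dss))
  if (sum(tri) == 0) stop("no N-free trinucleotide window in the input")
  ctxs <- names(di)
  counts <- matrix(0, 16L, 4L, dimnames = list(ctxs, DNA_BASES4))
  for (b in DNA_BASES4) counts[, b] <- tri[paste0(ctxs, b)]
  cond <- (counts + pseudocount) /
    (rowSums(counts) + 4 * pseudocount)
  cond[is.nan(cond)] <- 0.25  # unseen context: uninformative
  structure(list(context_counts = counts, cond_prob = cond,
                 dinuc_freq = di / sum(di), pseudocount = pseudocount),
            class = "markov2")
}

#' Uniform order-2 background
#'
#' Convenience constructor for the uniform background (every conditional and
#' dinucleotide probability equal), used as a neutral reference and by the
#' synthetic-data generator.
#'
#' @return A \code{"markov2"} object.
#' @export
uniform_markov2 <- function() {
  ctxs <- Biostrings::mkAllStrings(DNA_BASES4, 2L)
  counts <- matrix(0, 16L, 4L, dimnames = list(ctxs, DNA_BASES4))
  structure(list(context_counts = counts,
                 cond_prob = matrix(0.25, 16L, 4L,
                                    dimnames = list(ctxs, DNA_BASES4)),
                 dinuc_freq = stats::setNames(rep(1 / 16, 16L), ctxs),
                 pseudocount = 0),
            class = "markov2")
}

#' @export
print.markov2 <- function(x, ...) {
  n <- sum(x$context_counts)
  cat(sprintf("Order-2 Markov nucleotide background (%s context observations, pseudocount %g)\n",
              format(n, big.mark = ","), x$pseudocount))
  gc_ <- sum(x$dinuc_freq[c("CC", "CG", "GC", "GG")]) +
    0.5 * sum(x$dinuc_freq[c("AC", "AG", "CA", "CT", "GA", "GT", "TC", "TG")])
  cat(sprintf("  dinucleotide GC content: %.3f\n", gc_))
  invisible(x)
}

#' Simulate a sequence from a fitted background
#'
#' Draws \code{nsim} sequences of length \code{n} from the model: the initial
#' dinucleotide from the empirical dinucleotide distribution, every following
#' base from the conditional table. Uses R's RNG, so \code{set.seed()} makes
#' draws reproducible.
#'
#' @param object a \code{"markov2"} model.
#' @param nsim number of sequences.
#' @param seed optional seed passed to \code{set.seed}.
#' @param n sequence length in nucleotides.
#' @param ... unused.
#' @return Character vector of \code{nsim} sequences.
#' @export
simulate.markov2 <- function(object, nsim = 1, seed = NULL, n = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nsim), function(i)
    decode_dna(C_markov2_sample(as.integer(n), object$cond_prob,
                                as.numeric(object$dinuc_freq))), "")
}

#' Expected trinucleotide probabilities under the background
#'
#' \eqn{P(abc) = P(ab) \cdot P(c \mid ab)}, renormalised over the requested
#' support.
#'
#' @param model a \code{"markov2"} model.
#' @param support character vector of 3-mers (default: all 64).
#' @return Named probability vector over \code{support}, summing to 1.
#' @export
expected_triplet_probs <- function(model, support = NULL) {
  all3 <- Biostrings::mkAllStrings(DNA_BASES4, 3L)
  if (is.null(support)) support <- all3
  support <- toupper(support)
  if (length(support) == 0L) stop("support must be non-empty")
  if (!all(support %in% all3)) stop("support must consist of ACGT 3-mers")
  di <- substr(support, 1L, 2L)
  nb <- substr(support, 3L, 3L)
  p <- model$dinuc_freq[di] * model$cond_prob[cbind(di, nb)]
  names(p) <- support
  tot <- sum(p)
  if (tot == 0) stop("background assigns zero probability to the entire support")
  p / tot
}

# expected-prob floor for zero-background units (see chisq_unit_test)
floor_expected <- function(expected_probs, total_observed) {
  zero <- expected_probs == 0
  if (any(zero)) {
    expected_probs[zero] <- 1 / (10 * total_observed)
    expected_probs <- expected_probs / sum(expected_probs)
  }
  expected_probs
}

#' Chi-squared goodness-of-fit test of unit counts against a background
#'
#' Pearson chi-squared test of observed repeat-unit counts against expected
#' probabilities. Categories with expected count below \code{pool_threshold}
#' are pooled into a single category before the test (validity of the
#' asymptotic distribution); degrees of freedom are the number of categories
#' after pooling minus one. Units with zero background probability are given
#' an expected-probability floor of \code{1 / (10 * total observed)}.
#'
#' @param observed_counts named count vector (e.g. per 3-mer unit).
#' @param expected_probs named probability vector on the same support.
#' @param pool_threshold minimum expected count per unpooled category
#'   (default 5).
#' @return A list: \code{stat}, \code{df}, \code{p_value}, \code{n_pooled}.
#' @examples
#' chisq_unit_test(c(A = 30, B = 10), c(A = 0.5, B = 0.5))  # stat 10, df 1
#' @export
chisq_unit_test <- function(observed_counts, expected_probs,
                            pool_threshold = 5) {
  support <- names(observed_counts)
  if (is.null(support) || !all(support %in% names(expected_probs)))
    stop("expected_probs must cover the observed support")
  if (length(support) < 2L) stop("support of size 1 is degenerate")
  n <- sum(observed_counts)
  if (n < 1) stop("need at least one observation")
  p <- expected_probs[support]
  p <- floor_expected(p / sum(p), n)
  exp_counts <- n * p
  small <- exp_counts < pool_threshold
  if (sum(!small) < 1L || (sum(small) > 0L && sum(!small) < 1L))
    small <- rep(FALSE, length(p))  # nothing left to pool against
  if (any(small) && sum(small) >= 2L) {
    obs <- c(observed_counts[!small], pooled = sum(observed_counts[small]))
    ex <- c(exp_counts[!small], pooled = sum(exp_counts[small]))
  } else {
    obs <- observed_counts
    ex <- exp_counts
  }
  if (length(obs) < 2L) stop("fewer than 2 categories after pooling")
  stat <- sum((obs - ex)^2 / ex)
  df <- length(obs) - 1L
  list(stat = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_pooled = if (any(small) && sum(small) >= 2L) sum(small) else 0L)
}

#' Log-ratio profile of observed unit frequencies versus background
#'
#' Per-unit \code{log2(observed frequency / expected probability)}. Units in
#' the support with zero observed count are reported with \code{absent =
#' TRUE} and an \code{NA} log-ratio rather than \code{-Inf}.
#'
#' @param observed_counts named count vector.
#' @param expected_probs named probability vector covering the support.
#' @param log_base base of the logarithm (default 2).
#' @return Data frame: \code{unit}, \code{observed}, \code{observed_freq},
#'   \code{expected_prob}, \code{log_ratio}, \code{absent}.
#' @export
log_ratio_profile <- function(observed_counts, expected_probs, log_base = 2) {
  support <- names(observed_counts)
  if (is.null(support) || !all(support %in% names(expected_probs)))
    stop("expected_probs must cover the observed support")
  n <- sum(observed_counts)
  p <- expected_probs[support]
  p <- floor_expected(p / sum(p), max(n, 1))
  freq <- observed_counts / n
  lr <- ifelse(observed_counts > 0, log(freq / p, base = log_base), NA_real_)
  data.frame(unit = support, observed = as.vector(observed_counts),
             observed_freq = as.vector(freq), expected_prob = as.vector(p),
             log_ratio = as.vector(lr),
             absent = as.vector(observed_counts == 0),
             stringsAsFactors = FALSE)
}

#' Unit frequency profile of scanned tracts against a genomic background
#'
#' Aggregates the units of a (period-3-filtered) tract table, derives the
#' expected probabilities of those units under an order-2 Markov background,
#' and reports the log-ratio profile together with the chi-squared test of
#' the observed unit distribution against the background. The default
#' support is the set of units observed in the tracts. Reverse-complement
#' unit classes can optionally be merged (off by default, matching
#' plus-strand reporting).
#'
#' @param tracts tract table (period-3 filtered).
#' @param model a \code{"markov2"} background.
#' @param merge_revcomp merge each unit with its reverse complement
#'   (default \code{FALSE}).
#' @param log_base base for the log-ratio (default 2).
#' @return An object of class \code{"unit_profile"}: the \code{profile} data
#'   frame (see \code{\link{log_ratio_profile}}), \code{chisq} (see
#'   \code{\link{chisq_unit_test}}), \code{n_tracts}.
#' @export
unit_frequency_profile <- function(tracts, model, merge_revcomp = FALSE,
                                   log_base = 2) {
  if (nrow(tracts) == 0L) stop("no tracts to profile")
  units <- toupper(tracts$unit)
  if (merge_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(units)))
    units <- pmin(canonical_unit(units), canonical_unit(rc))
  }
  obs <- table(units)
  observed <- stats::setNames(as.integer(obs), names(obs))
  if (merge_revcomp) {
    all3 <- Biostrings::mkAllStrings(DNA_BASES4, 3L)
    rc3 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(all3)))
    cls <- pmin(canonical_unit(all3), canonical_unit(rc3))
    base_p <- expected_triplet_probs(model, all3)
    expected <- tapply(base_p, cls, sum)[names(observed)]
    expected <- expected / sum(expected)
  } else {
    expected <- expected_triplet_probs(model, names(observed))
  }
  structure(list(profile = log_ratio_profile(observed, expected, log_base),
                 chisq = chisq_unit_test(observed, expected),
                 n_tracts = nrow(tracts)),
            class = "unit_profile")
}

#' @export
print.unit_profile <- function(x, ...) {
  cat(sprintf("Repeat unit frequency profile: %d tracts, %d distinct units\n",
              x$n_tracts, nrow(x$profile)))
  cat(sprintf("  chi-squared vs background: stat %.2f, df %d, p %.3g\n",
              x$chisq$stat, x$chisq$df, x$chisq$p_value))
  top <- x$profile[order(-abs(ifelse(is.na(x$profile$log_ratio), 0,
                                     x$profile$log_ratio))), ]
  cat("  strongest deviations (unit: log-ratio):\n")
  for (i in seq_len(min(5L, nrow(top))))
    cat(sprintf("    %s: %+0.2f\n", top$unit[i], top$log_ratio[i]))
  invisible(x)
}

#' Serialise / load a background model as TSV
#'
#' @param model a \code{"markov2"} model.
#' @param path file path.
#' @return \code{write_markov2_tsv} returns \code{path} invisibly;
#'   \code{read_markov2_tsv} returns the model.
#' @export
write_markov2_tsv <- function(model, path) {
  ctx <- rownames(model$context_counts)
  long <- data.frame(
    context = rep(ctx, each = 4L),
    base = rep(DNA_BASES4, times = 16L),
    count = as.vector(t(model$context_counts)),
    prob = as.vector(t(model$cond_prob)),
    dinuc_freq = rep(as.vector(model$dinuc_freq), each = 4L),
    pseudocount = model$pseudocount)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markov2_tsv
#' @export
read_markov2_tsv <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  ctx <- unique(long$context)
  counts <- matrix(long$count, nrow = 16L, byrow = TRUE,
                   dimnames = list(ctx, DNA_BASES4))
  cond <- matrix(long$prob, nrow = 16L, byrow = TRUE,
                 dimnames = list(ctx, DNA_BASES4))
  dinuc <- stats::setNames(long$dinuc_freq[seq(1L, nrow(long), by = 4L)], ctx)
  structure(list(context_counts = counts, cond_prob = cond,
                 dinuc_freq = dinuc, pseudocount = long$pseudocount[1L]),
            class = "markov2")
}
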