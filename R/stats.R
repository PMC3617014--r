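#' Exact two-tailed binomial test (minimum-likelihood rule)
#'
#' The two-tailed p-value is the sum of \code{Binomial(n, p0)} probabilities
#' of all outcomes whose probability does not exceed that of the observed
#' \code{k} (up to a small relative tolerance for floating-point ties).
#' When \code{p0} is 0 or 1 the test degenerates: p is 1 if \code{k} is the
#' only possible outcome, 0 otherwise.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return Two-tailed p-value.
#' @examples
#' binomial_composition_test(10, 10, 0.5)  # 2/1024
#' @export
binomial_composition_test <- function(k, n, p0) {
  if (k < 0 || k > n) stop("k must be in [0, n]")
  if (p0 <= 0 || p0 >= 1) {
    consistent <- (p0 <= 0 && k == 0) || (p0 >= 1 && k == n)
    return(if (consistent) 1 else 0)
  }
  pmf <- stats::dbinom(0:n, n, p0)
  min(1, sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)]))
}

#' Per-residue composition analysis of TNR- vs variant-encoded tracts
#'
#' For every residue with at least one homo-AA tract: trials are the tracts
#' of that residue, successes the TNR-encoded ones, and the null success
#' probability is the proportion of TNR-encoded homo-AA proteins among all
#' homo-AA proteins (a protein-level proportion, kept deliberately as
#' stated even though trials are tract counts). The reported log-ratio is
#' \code{log2} of the residue's share among TNR-encoded tracts over its
#' share among variant-encoded tracts.
#'
#' @param tracts homo-AA tract table (classified).
#' @param protein_sets from \code{\link{build_protein_sets}}.
#' @param alpha significance level (default 0.05).
#' @return Data frame per residue: \code{residue}, \code{n_tracts_total},
#'   \code{n_tnr_tracts}, \code{p0}, \code{p_value},
#'   \code{log2_proportion_ratio}, \code{significant}.
#' @export
composition_analysis <- function(tracts, protein_sets, alpha = 0.05) {
  if (nrow(tracts) == 0L) stop("no tracts")
  p0 <- length(protein_sets$tnr) / length(protein_sets$all)
  res <- sort(unique(tracts$residue))
  n_tnr_all <- sum(tracts$encoding_class == "tnr")
  n_var_all <- sum(tracts$encoding_class == "variant")
  out <- lapply(res, function(r) {
    sub <- tracts[tracts$residue == r, ]
    n <- nrow(sub)
    k <- sum(sub$encoding_class == "tnr")
    share_tnr <- if (n_tnr_all > 0) k / n_tnr_all else NA_real_
    share_var <- if (n_var_all > 0) (n - k) / n_var_all else NA_real_
    lr <- if (!is.na(share_tnr) && !is.na(share_var) &&
              share_tnr > 0 && share_var > 0)
      log2(share_tnr / share_var) else NA_real_
    p <- binomial_composition_test(k, n, p0)
    data.frame(residue = r, n_tracts_total = n, n_tnr_tracts = k, p0 = p0,
               p_value = p, log2_proportion_ratio = lr,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# exact permutation null of the rank-sum statistic, ties allowed:
# subset-sum DP over doubled midranks; counts fit in doubles for n <= 40.
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r2 <- as.integer(round(2 * rank(c(x, y))))
  u_obs <- sum(r2[seq_len(n1)]) / 2 - n1 * (n1 + 1) / 2
  smax <- sum(r2)
  # dp[k+1, s+1] = number of k-subsets of r2 with doubled-rank sum s
  dp <- matrix(0, n1 + 1L, smax + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(n1, n1)  # full column update, top-down in k
    for (k in kmax:1) {
      src <- dp[k, 1:(smax + 1L - v)]
      if (any(src != 0))
        dp[k + 1L, (v + 1L):(smax + 1L)] <-
          dp[k + 1L, (v + 1L):(smax + 1L)] + src
    }
  }
  counts <- dp[n1 + 1L, ]
  sums2 <- 0:smax
  u_all <- sums2 / 2 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  extreme <- abs(u_all - mu) >= abs(u_obs - mu) - 1e-9
  sum(counts[extreme]) / choose(n, n1)
}

#' Mann-Whitney U test
#'
#' Rank-based comparison of two samples. The exact permutation null of the
#' rank-sum statistic (ties handled via midranks) is enumerated when
#' \code{n1 * n2} does not exceed \code{exact_limit}; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' The two-sided p-value in exact mode is the probability of a U at least
#' as far from its null mean as observed.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_limit switch to the normal approximation when
#'   \code{length(x) * length(y)} exceeds this (default 400).
#' @return List with \code{U} (for \code{x}), \code{p_value},
#'   \code{method} (\code{"exact"} or \code{"normal"}).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= exact_limit) {
    return(list(U = U, p_value = min(1, mw_exact_p(x, y)), method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Per-residue length comparison of TNR- vs variant-encoded tracts
#'
#' For every residue present in both encoding classes, compares tract
#' lengths with \code{\link{mann_whitney_u}} and reports means, standard
#' errors, the log2 ratio of means and the p-value. Residues present in a
#' single class are reported with an \code{NA} p-value.
#'
#' @param tracts homo-AA tract table (classified).
#' @param alpha significance level (default 0.05).
#' @return Data frame per residue: counts, \code{mean_tnr},
#'   \code{se_tnr}, \code{mean_variant}, \code{se_variant}, \code{U},
#'   \code{p_value}, \code{log2_length_ratio}, \code{significant}.
#' @export
length_analysis <- function(tracts, alpha = 0.05) {
  if (nrow(tracts) == 0L) stop("no tracts")
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
  else NA_real_
  out <- lapply(sort(unique(tracts$residue)), function(r) {
    lt <- tracts$length[tracts$residue == r & tracts$encoding_class == "tnr"]
    lv <- tracts$length[tracts$residue == r &
                          tracts$encoding_class == "variant"]
    if (length(lt) > 0L && length(lv) > 0L) {
      mw <- mann_whitney_u(lt, lv)
      U <- mw$U; p <- mw$p_value
      lr <- log2(mean(lt) / mean(lv))
    } else {
      U <- NA_real_; p <- NA_real_; lr <- NA_real_
    }
    data.frame(residue = r, n_tnr = length(lt), n_variant = length(lv),
               mean_tnr = if (length(lt)) mean(lt) else NA_real_,
               se_tnr = if (length(lt)) se(lt) else NA_real_,
               mean_variant = if (length(lv)) mean(lv) else NA_real_,
               se_variant = if (length(lv)) se(lv) else NA_real_,
               U = U, p_value = p, log2_length_ratio = lr,
               significant = !is.na(p) & p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare interaction degrees of TNR- vs variant-encoded proteins
#'
#' Degree is the number of distinct interaction partners in an undirected
#' pair list (duplicate pairs and self-pairs ignored); proteins absent from
#' the pair list have degree 0. Degrees of the TNR-encoded and
#' variant-encoded protein sets are compared with the Mann-Whitney U test.
#'
#' @param ppi_pairs data frame with columns \code{protein_a},
#'   \code{protein_b} (may have zero rows).
#' @param protein_sets from \code{\link{build_protein_sets}}.
#' @return List: \code{degrees} (data frame \code{protein_id},
#'   \code{degree}, \code{set}), \code{U}, \code{p_value}.
#' @export
ppi_degree_comparison <- function(ppi_pairs, protein_sets) {
  deg_of <- function(ids) {
    vapply(ids, function(p) {
      partners <- c(ppi_pairs$protein_b[ppi_pairs$protein_a == p],
                    ppi_pairs$protein_a[ppi_pairs$protein_b == p])
      length(unique(setdiff(partners, p)))
    }, 0L)
  }
  dt <- deg_of(protein_sets$tnr)
  dv <- deg_of(protein_sets$variant)
  degrees <- rbind(
    data.frame(protein_id = protein_sets$tnr, degree = as.integer(dt),
               set = "tnr", stringsAsFactors = FALSE),
    data.frame(protein_id = protein_sets$variant, degree = as.integer(dv),
               set = "variant", stringsAsFactors = FALSE))
  if (length(dt) == 0L || length(dv) == 0L ||
      (all(dt == dt[1L]) && all(dv == dt[1L]))) {
    return(list(degrees = degrees, U = NA_real_, p_value = 1))
  }
  mw <- mann_whitney_u(as.numeric(dt), as.numeric(dv))
  list(degrees = degrees, U = mw$U, p_value = mw$p_value)
}

#' Compare per-tract conservation of TNR- vs variant-encoded tracts
#'
#' The per-tract metric is the mean per-base conservation score over the
#' tract's genomic loci; bases missing from the score track are excluded
#' from the mean (not treated as 0). Tracts with no covered base get an
#' \code{NA} metric and are excluded from the class comparison, with a
#' warning. Classes are compared with the Mann-Whitney U test.
#'
#' @param tracts homo-AA tract table with a \code{genomic_loci} column.
#' @param scores per-base score table in bedGraph convention: data frame
#'   \code{seqid}, 0-based half-open \code{start}, \code{end},
#'   \code{score}.
#' @return List: \code{tract_scores} (tract table plus
#'   \code{mean_conservation}), \code{U}, \code{p_value}.
#' @export
tract_conservation_comparison <- function(tracts, scores) {
  sgr <- GenomicRanges::GRanges(scores$seqid,
                                IRanges::IRanges(scores$start + 1L,
                                                 scores$end))
  sgr$score <- scores$score
  metric <- rep(NA_real_, nrow(tracts))
  loci <- parse_loci(tracts$genomic_loci)
  for (i in seq_len(nrow(tracts))) {
    li <- loci[[i]]
    if (nrow(li) == 0L) next
    q <- GenomicRanges::GRanges(li$seqid,
                                IRanges::IRanges(li$start + 1L, li$end))
    # sequences absent from the score track are simply uncovered
    h <- suppressWarnings(GenomicRanges::findOverlaps(q, sgr))
    if (length(h) == 0L) next
    w <- GenomicRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(h)], sgr[S4Vectors::subjectHits(h)]))
    sc <- sgr$score[S4Vectors::subjectHits(h)]
    metric[i] <- sum(w * sc) / sum(w)
  }
  if (anyNA(metric))
    warning(sum(is.na(metric)),
            " tract(s) without covered bases excluded from the comparison")
  tracts$mean_conservation <- metric
  mt <- metric[tracts$encoding_class == "tnr" & !is.na(metric)]
  mv <- metric[tracts$encoding_class == "variant" & !is.na(metric)]
  if (length(mt) == 0L || length(mv) == 0L ||
      (length(unique(c(mt, mv))) == 1L)) {
    return(list(tract_scores = tracts, U = NA_real_, p_value = 1))
  }
  mw <- mann_whitney_u(mt, mv)
  list(tract_scores = tracts, U = mw$U, p_value = mw$p_value)
}
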