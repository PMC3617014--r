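test_that("two-tailed binomial p matches full pmf enumeration", {
  # frozen small cases, computed by enumerating the pmf
  expect_equal(binomial_composition_test(10, 10, 0.5), 2 / 1024)
  expect_equal(binomial_composition_test(2, 2, 0.5), 0.5)
  # modal outcome -> p = 1
  expect_equal(binomial_composition_test(5, 10, 0.5), 1)
  # degenerate null probabilities
  expect_equal(binomial_composition_test(0, 5, 1e-300), 1)
  expect_equal(binomial_composition_test(3, 5, 1 - 1e-16), 0)

  # exhaustive grid vs an independent enumeration oracle
  for (n in 1:12) for (p0 in seq(0.1, 0.9, by = 0.1)) {
    pmf <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
                  0)
    for (k in 0:n) {
      oracle <- min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
      expect_equal(binomial_composition_test(k, n, p0), oracle,
                   info = sprintf("n=%d k=%d p0=%g", n, k, p0))
    }
  }
})

test_that("binomial test agrees with stats::binom.test", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_composition_test(k, n, p0),
                 binom.test(k, n, p0)$p.value, tolerance = 1e-12,
                 info = sprintf("n=%d k=%d p0=%g", n, k, p0))
  }
})

test_that("Mann-Whitney exact p equals permutation enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 labelings as extreme
  expect_equal(r$method, "exact")

  # identical samples with ties: no evidence at all
  r2 <- mann_whitney_u(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_gte(r2$p_value, 0.99)

  # independent enumeration over all C(n, n1) labelings, with ties
  enum_p <- function(x, y) {
    v <- c(x, y)
    n1 <- length(x)
    rk <- rank(v)
    mu <- n1 * length(y) / 2
    uo <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- combn(length(v), n1)
    us <- apply(combs, 2, function(idx)
      sum(rk[idx]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mu) >= abs(uo - mu) - 1e-9)
  }
  set.seed(19)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    r <- mann_whitney_u(x, y)
    expect_equal(r$p_value, enum_p(x, y), info = i)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney switches to a tie-corrected normal approximation", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(30) + 1   # n1*n2 = 900 > 400
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal")
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-9)
  # tie-heavy large samples still agree with wilcox.test's tie correction
  x2 <- sample(1:5, 30, TRUE); y2 <- sample(1:5, 30, TRUE)
  r2 <- mann_whitney_u(x2, y2)
  w2 <- wilcox.test(x2, y2, exact = FALSE, correct = TRUE)
  expect_equal(r2$p_value, w2$p.value, tolerance = 1e-9)
})

mk_tracts <- function(residue, class, lengths, proteins = NULL) {
  n <- length(lengths)
  data.frame(protein_id = proteins %||% paste0("p", seq_len(n), "_",
                                               residue, "_", class),
             gene_id = "g", residue = residue,
             start = 0L, end = lengths, length = lengths,
             encoding_class = class, max_same_codon_run = 1L,
             genomic_loci = NA_character_, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("composition_analysis flags residues off the protein-level p0", {
  # 30 Q tracts all TNR vs 30 A tracts all variant: p0 = 0.5
  tr <- rbind(mk_tracts("Q", "tnr", rep(10, 30)),
              mk_tracts("A", "variant", rep(10, 30)))
  sets <- build_protein_sets(tr)
  expect_equal(length(sets$tnr), 30L)
  res <- composition_analysis(tr, sets)
  q <- res[res$residue == "Q", ]
  expect_equal(q$n_tracts_total, 30L)
  expect_equal(q$n_tnr_tracts, 30L)
  expect_equal(q$p0, 0.5)
  expect_equal(q$p_value, binomial_composition_test(30, 30, 0.5))
  expect_true(q$significant)
  # Q is 100% of tnr tracts and 0% of variant tracts: ratio undefined -> NA
  expect_true(is.na(q$log2_proportion_ratio))
  expect_equal(sum(res$n_tracts_total), nrow(tr))
})

test_that("length_analysis reports means, ratios and exact p-values", {
  tr <- rbind(mk_tracts("Q", "tnr", c(12, 14, 16)),
              mk_tracts("Q", "variant", c(7, 8, 9)),
              mk_tracts("A", "tnr", c(9, 9)))
  res <- length_analysis(tr)
  q <- res[res$residue == "Q", ]
  expect_equal(q$mean_tnr, 14)
  expect_equal(q$mean_variant, 8)
  expect_equal(q$log2_length_ratio, log2(14 / 8))
  expect_equal(q$p_value, 0.1)  # complete separation, 3 vs 3
  a <- res[res$residue == "A", ]
  expect_true(is.na(a$p_value))  # single class only
  # one tract per class, equal lengths: p = 1
  tr2 <- rbind(mk_tracts("S", "tnr", 9), mk_tracts("S", "variant", 9))
  expect_equal(length_analysis(tr2)$p_value, 1)
})

test_that("PPI degrees count distinct partners and empty tables give p = 1", {
  sets <- list(tnr = c("p1", "p2"), variant = c("p3", "p4"),
               all = c("p1", "p2", "p3", "p4"))
  empty <- data.frame(protein_a = character(0), protein_b = character(0))
  r0 <- ppi_degree_comparison(empty, sets)
  expect_equal(r0$p_value, 1)
  expect_true(all(r0$degrees$degree == 0L))

  # duplicate pair and a self-pair: p1 has 2 distinct partners
  ppi <- data.frame(protein_a = c("p1", "p1", "p3", "p1"),
                    protein_b = c("p3", "p3", "p1", "p1"),
                    stringsAsFactors = FALSE)
  r <- ppi_degree_comparison(ppi, sets)
  d <- setNames(r$degrees$degree, r$degrees$protein_id)
  expect_equal(unname(d["p1"]), 1L)  # p3 counted once, self-pair dropped
  ppi2 <- rbind(ppi, data.frame(protein_a = "p4", protein_b = "p1"))
  r2 <- ppi_degree_comparison(ppi2, sets)
  d2 <- setNames(r2$degrees$degree, r2$degrees$protein_id)
  expect_equal(unname(d2["p1"]), 2L)
})

test_that("conservation metric is the covered-base-weighted mean", {
  tr <- rbind(mk_tracts("Q", "tnr", 2), mk_tracts("Q", "variant", 2))
  tr$genomic_loci <- c("chr1:100-103;chr1:200-203", "chr1:100-106")
  scores <- data.frame(seqid = "chr1",
                       start = c(100L, 200L), end = c(103L, 203L),
                       score = c(0, 1))
  r <- tract_conservation_comparison(tr, scores)
  expect_equal(r$tract_scores$mean_conservation[1], 0.5)
  # second tract: only [100,103) covered, score 0
  expect_equal(r$tract_scores$mean_conservation[2], 0)

  # constant track: every mean equal, p = 1
  scores2 <- data.frame(seqid = "chr1", start = 0L, end = 1000L,
                        score = 0.8)
  r2 <- tract_conservation_comparison(tr, scores2)
  expect_equal(r2$tract_scores$mean_conservation, c(0.8, 0.8))
  expect_equal(r2$p_value, 1)

  # uncovered tract excluded with a warning
  tr3 <- tr
  tr3$genomic_loci[2] <- "chr2:5-8"
  expect_warning(r3 <- tract_conservation_comparison(tr3, scores),
                 "excluded")
  expect_true(is.na(r3$tract_scores$mean_conservation[2]))
})
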