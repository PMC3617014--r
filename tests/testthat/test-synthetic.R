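test_that("invalid configurations are rejected", {
  expect_error(simulation_config(homoaa_spec = data.frame(
    residue = "Q", theta = 1.2, tnr_mean = 9, variant_mean = 9,
    n_tracts = 5L)), "theta")
  expect_error(simulation_config(homoaa_spec = data.frame(
    residue = "Q", theta = 0.5, tnr_mean = 5, variant_mean = 9,
    n_tracts = 5L)), ">= 7")
  # single-codon residues cannot be variant-encoded
  expect_error(simulation_config(homoaa_spec = data.frame(
    residue = "M", theta = 0.5, tnr_mean = 9, variant_mean = 9,
    n_tracts = 5L)), "variant encoding impossible")
  expect_error(simulation_config(ontology_spec = list(
    n_terms = 10L, dag_depth = 0L, enrichment_odds = 1,
    base_rate = 0.1)), "dag_depth")
  expect_error(simulation_config(planted_tnrs = data.frame(
    unit = "TAA", copies = 10L, mismatches = 0L,
    region_class = "exonic")), "stop codon")
  expect_error(simulation_config(n_genes = 20L), "n_genes too small")
})

test_that("generation is byte-deterministic in the seed", {
  cfg <- small_sim_config(seed = 21)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  simulate_dataset(small_sim_config(seed = 22), d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_false(identical(readLines(file.path(d1, "genome.fasta")),
                         readLines(file.path(d3, "genome.fasta"))))
})

test_that("a trivial single-tract genome is constructed exactly", {
  cfg <- simulation_config(
    seed = 3, genome_length = 20000L, n_genes = 2L,
    planted_tnrs = data.frame(unit = "CAG", copies = 20L, mismatches = 0L,
                              region_class = "intergenic"),
    homoaa_spec = data.frame(residue = "Q", theta = 1, tnr_mean = 8,
                             variant_mean = 8, n_tracts = 2L),
    ontology_spec = list(n_terms = 5L, dag_depth = 1L,
                         enrichment_odds = 1, base_rate = 0.2))
  sim <- generate_genome(cfg)
  tt <- sim$truth_tracts
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$end - tt$start, 60L)
  planted <- paste(sim$genome_bases[(tt$start + 1L):tt$end], collapse = "")
  expect_equal(planted, strrep("CAG", 20))
})

test_that("a constrained background spec shapes the emitted sequence", {
  cond <- matrix(0.25, 16, 4)
  rownames(cond) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2)
  colnames(cond) <- c("A", "C", "G", "T")
  cond["CC", ] <- c(0, 0, 1, 0)   # G always follows CC
  cfg <- simulation_config(
    seed = 4, genome_length = 30000L, n_genes = 2L,
    markov_spec = list(cond_prob = cond),
    planted_tnrs = data.frame(unit = character(0), copies = integer(0),
                              mismatches = integer(0),
                              region_class = character(0)),
    homoaa_spec = data.frame(residue = "Q", theta = 1, tnr_mean = 8,
                             variant_mean = 8, n_tracts = 2L),
    ontology_spec = list(n_terms = 5L, dag_depth = 1L,
                         enrichment_odds = 1, base_rate = 0.2))
  sim <- generate_genome(cfg)
  b <- sim$genome_bases
  cc <- which(b[-length(b)] == "C" & b[-1] == "C")
  cc <- cc[cc + 2 <= length(b)]
  expect_gt(length(cc), 100)
  expect_true(all(b[cc + 2] == "G"))
})

test_that("theta = 1 and theta = 0 produce the promised codon patterns", {
  mk <- function(theta) simulation_config(
    seed = 6, genome_length = 60000L, n_genes = 20L,
    planted_tnrs = data.frame(unit = character(0), copies = integer(0),
                              mismatches = integer(0),
                              region_class = character(0)),
    homoaa_spec = data.frame(residue = "Q", theta = theta, tnr_mean = 10,
                             variant_mean = 10, n_tracts = 12L),
    ontology_spec = list(n_terms = 5L, dag_depth = 1L,
                         enrichment_odds = 1, base_rate = 0.2))
  for (theta in c(1, 0)) {
    sim <- generate_gene_models(mk(theta), generate_genome(mk(theta)))
    truth <- sim$truth_homoaa
    expect_true(all(truth$encoding_class ==
                      if (theta == 1) "tnr" else "variant"))
    for (i in seq_len(nrow(truth))) {
      cds <- sim$cds[[truth$gene_id[i]]]
      cod <- substring(cds, 3 * (truth$start[i]:(truth$end[i] - 1)) + 1,
                       3 * (truth$start[i]:(truth$end[i] - 1)) + 3)
      expect_true(all(cod %in% c("CAA", "CAG")), info = i)
      mx <- max(rle(cod)$lengths)
      if (theta == 1) expect_gte(mx, 7) else expect_lte(mx, 6)
    }
  }
})

test_that("planted run lengths are >= 7 and scale with the mean", {
  cfg <- small_sim_config(seed = 31)
  sim <- generate_gene_models(cfg, generate_genome(cfg))
  truth <- sim$truth_homoaa
  expect_true(all(truth$length >= 7L))
  q <- truth[truth$residue == "Q", ]
  expect_gt(mean(q$length[q$encoding_class == "tnr"]),
            mean(q$length[q$encoding_class == "variant"]))
})

test_that("the ontology is a rooted DAG and odds = 1 plants no signal", {
  cfg <- small_sim_config(seed = 41,
                          ontology_spec = list(n_terms = 40L,
                                               dag_depth = 3L,
                                               enrichment_odds = 1,
                                               base_rate = 0.2))
  sim <- generate_ontology_and_associations(
    cfg, generate_gene_models(cfg, generate_genome(cfg)))
  ont <- parse_obo(text = sim$obo_lines)
  expect_equal(nrow(ont$terms), 40L)
  expect_equal(ont$roots, "GO:0000001")
  # every term reaches the root
  for (t in sample(ont$terms$id, 10))
    expect_true("GO:0000001" %in% go_ancestors(ont, t))
  # odds 1: association of the planted term independent of repeat status
  tnr_genes <- unique(sim$truth_homoaa$gene_id[
    sim$truth_homoaa$encoding_class == "tnr"])
  has_term <- sim$protein_map$gene_id %in%
    sim$associations$gene_id[sim$associations$term_id == sim$planted_term]
  is_tnr <- sim$protein_map$gene_id %in% tnr_genes
  p <- suppressWarnings(chisq.test(table(has_term, is_tnr))$p.value)
  expect_gt(p, 0.001)
})

test_that("planted enrichment odds are recovered from the associations", {
  # aggregate over seeds to beat sampling noise in the odds-ratio estimate
  or_hat <- vapply(1:4, function(s) {
    cfg <- small_sim_config(seed = 300 + s,
                            ontology_spec = list(n_terms = 30L,
                                                 dag_depth = 3L,
                                                 enrichment_odds = 5,
                                                 base_rate = 0.15))
    sim <- generate_ontology_and_associations(
      cfg, generate_gene_models(cfg, generate_genome(cfg)))
    tnr_genes <- unique(sim$truth_homoaa$gene_id[
      sim$truth_homoaa$encoding_class == "tnr"])
    has <- sim$protein_map$gene_id %in%
      sim$associations$gene_id[sim$associations$term_id ==
                                 sim$planted_term]
    tnr <- sim$protein_map$gene_id %in% tnr_genes
    (sum(has & tnr) + 0.5) * (sum(!has & !tnr) + 0.5) /
      ((sum(has & !tnr) + 0.5) * (sum(!has & tnr) + 0.5))
  }, 0)
  expect_gt(exp(mean(log(or_hat))), 2.5)
  expect_lt(exp(mean(log(or_hat))), 10)
})

test_that("PPI pairs are unique, non-self, and empty at degree 0", {
  cfg <- small_sim_config(seed = 51, ppi_spec = list(mean_degree = 3))
  sim <- generate_ppi_and_conservation(
    cfg, generate_gene_models(cfg, generate_genome(cfg)))
  ppi <- sim$ppi
  expect_gt(nrow(ppi), 0L)
  expect_true(all(ppi$protein_a != ppi$protein_b))
  key <- paste(pmin(ppi$protein_a, ppi$protein_b),
               pmax(ppi$protein_a, ppi$protein_b))
  expect_equal(anyDuplicated(key), 0L)

  cfg0 <- small_sim_config(seed = 51, ppi_spec = list(mean_degree = 0))
  sim0 <- generate_ppi_and_conservation(
    cfg0, generate_gene_models(cfg0, generate_genome(cfg0)))
  expect_equal(nrow(sim0$ppi), 0L)
})

test_that("conservation scores cover gene bodies, clipped to [0, 1]", {
  cfg <- small_sim_config(seed = 61,
                          conservation_spec = list(baseline = 0.8, sd = 0))
  sim <- generate_ppi_and_conservation(
    cfg, generate_gene_models(cfg, generate_genome(cfg)))
  cons <- sim$conservation
  expect_true(all(cons$score == 0.8))   # zero noise: constant baseline
  gl <- sim$gene_layout
  covered <- sum(cons$end - cons$start)
  expect_equal(covered, sum(gl$end0 - gl$start0))
  cfg2 <- small_sim_config(seed = 61,
                           conservation_spec = list(baseline = 0.95,
                                                    sd = 0.3))
  sim2 <- generate_ppi_and_conservation(
    cfg2, generate_gene_models(cfg2, generate_genome(cfg2)))
  expect_true(all(sim2$conservation$score >= 0 &
                    sim2$conservation$score <= 1))
})

test_that("scanner closure: planted pure tracts recovered at exact loci", {
  # 50 planted tracts across units, copies and both strands of gene space
  units <- c("CAG", "CTG", "AAT", "GCC", "ACT", "CGG", "TTA", "GAT")
  plants <- data.frame(unit = rep(units, length.out = 38L),
                       copies = rep(c(7L, 8L, 10L, 12L, 15L, 20L),
                                    length.out = 38L),
                       mismatches = 0L, region_class = "intergenic",
                       stringsAsFactors = FALSE)
  genic <- data.frame(unit = c("CAG", "CTG", "CAG", "CGG", "CAG", "GCA",
                               rep("CAG", 6)),
                      copies = c(12L, 10L, 10L, 9L, 15L, 8L,
                                 rep(10L, 6)),
                      mismatches = 0L,
                      region_class = c("intron", "intron", "utr5", "utr3",
                                       "upstream", "exonic", "exonic",
                                       "intron", "utr5", "utr3",
                                       "upstream", "exonic"),
                      stringsAsFactors = FALSE)
  cfg <- simulation_config(
    seed = 71, genome_length = 200000L, n_genes = 40L,
    planted_tnrs = rbind(plants, genic),
    homoaa_spec = data.frame(residue = "Q", theta = 0.5, tnr_mean = 9,
                             variant_mean = 9, n_tracts = 20L),
    ontology_spec = list(n_terms = 10L, dag_depth = 2L,
                         enrichment_odds = 1, base_rate = 0.2))
  sim <- generate_gene_models(cfg, generate_genome(cfg))
  genome <- c(chr1 = paste(sim$genome_bases, collapse = ""))
  tr <- scan_tnr(genome)
  truth <- sim$truth_tracts
  pure <- truth[truth$mismatches == 0 & truth$end - truth$start >= 20, ]
  expect_gte(nrow(pure), 50L)
  got <- paste(tr$start, tr$end)
  expect_true(all(paste(pure$start, pure$end) %in% got))
  # and the reported units match the forward-strand truth
  m <- merge(pure, tr, by = c("start", "end"))
  expect_equal(m$unit.x, m$unit.y)
})

test_that("truth region classes are recovered by localization", {
  sim <- simulate_dataset(small_sim_config(seed = 81))
  dir <- tempfile(); dir.create(dir)
  writeLines(sim$gff_lines, file.path(dir, "a.gff3"))
  models <- load_annotation(file.path(dir, "a.gff3"))
  truth <- sim$truth_tracts
  loc <- localize_tracts(truth[, c("sequence_id", "start", "end")], models)
  agree <- mean(loc$region_class == truth$region_class)
  expect_gte(agree, 0.99)
})
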