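# A small hand-built annotation: two genes on chr1.
#  - gA (+): two splice variants; v2 has the longer CDS.
#  - gB (+): starts 400 nt downstream of gA's end, so gA's body lies inside
#    gB's upstream window.
fixture_gff <- function() {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.v1;Parent=gA;protein_id=pA1",
    "chr1\ttest\texon\t1001\t1400\t.\t+\t.\tID=gA.v1.e1;Parent=gA.v1",
    "chr1\ttest\texon\t1601\t2000\t.\t+\t.\tID=gA.v1.e2;Parent=gA.v1",
    "chr1\ttest\tfive_prime_UTR\t1001\t1100\t.\t+\t.\tID=gA.v1.u5;Parent=gA.v1",
    "chr1\ttest\tCDS\t1101\t1400\t.\t+\t0\tID=gA.v1.c1;Parent=gA.v1",
    "chr1\ttest\tCDS\t1601\t1699\t.\t+\t0\tID=gA.v1.c2;Parent=gA.v1",
    "chr1\ttest\tthree_prime_UTR\t1700\t2000\t.\t+\t.\tID=gA.v1.u3;Parent=gA.v1",
    "chr1\ttest\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.v2;Parent=gA;protein_id=pA2",
    "chr1\ttest\texon\t1001\t1400\t.\t+\t.\tID=gA.v2.e1;Parent=gA.v2",
    "chr1\ttest\texon\t1601\t2000\t.\t+\t.\tID=gA.v2.e2;Parent=gA.v2",
    "chr1\ttest\tfive_prime_UTR\t1001\t1100\t.\t+\t.\tID=gA.v2.u5;Parent=gA.v2",
    "chr1\ttest\tCDS\t1101\t1400\t.\t+\t0\tID=gA.v2.c1;Parent=gA.v2",
    "chr1\ttest\tCDS\t1601\t1765\t.\t+\t0\tID=gA.v2.c2;Parent=gA.v2",
    "chr1\ttest\tthree_prime_UTR\t1766\t2000\t.\t+\t.\tID=gA.v2.u3;Parent=gA.v2",
    "chr1\ttest\tgene\t2401\t3000\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t2401\t3000\t.\t-\t.\tID=gB.v1;Parent=gB;protein_id=pB",
    "chr1\ttest\texon\t2401\t3000\t.\t-\t.\tID=gB.v1.e1;Parent=gB.v1",
    "chr1\ttest\tfive_prime_UTR\t2901\t3000\t.\t-\t.\tID=gB.v1.u5;Parent=gB.v1",
    "chr1\ttest\tCDS\t2502\t2900\t.\t-\t0\tID=gB.v1.c1;Parent=gB.v1",
    "chr1\ttest\tthree_prime_UTR\t2401\t2501\t.\t-\t.\tID=gB.v1.u3;Parent=gB.v1")
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

test_that("one splice variant is kept per gene, by rule", {
  path <- fixture_gff()
  m_long <- load_annotation(path)
  expect_equal(m_long$models$gA$mrna_id, "gA.v2")  # CDS 465 > 399
  expect_equal(m_long$models$gA$protein_id, "pA2")
  m_first <- load_annotation(path, variant_rule = "first_listed")
  expect_equal(m_first$models$gA$mrna_id, "gA.v1")
  # single-variant gene kept under either rule
  expect_equal(m_long$models$gB$mrna_id, "gB.v1")
  expect_equal(m_first$models$gB$mrna_id, "gB.v1")
})

test_that("genes without CDS or with broken frames are dropped, loudly", {
  lines <- c("##gff-version 3",
             "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
             "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
             "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1",
             "chr1\tt\tgene\t201\t300\t.\t+\t.\tID=g2",
             "chr1\tt\tmRNA\t201\t300\t.\t+\t.\tID=t2;Parent=g2",
             "chr1\tt\texon\t201\t300\t.\t+\t.\tID=e2;Parent=t2",
             "chr1\tt\tCDS\t201\t300\t.\t+\t0\tID=c2;Parent=t2")
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  expect_warning(expect_warning(m <- load_annotation(path),
                                "without CDS"),
                 "not divisible by 3")
  expect_length(m$models, 0L)
})

test_that("a sequence blacklist excludes whole sequences", {
  path <- fixture_gff()
  m <- load_annotation(path, exclude_seqs = "chr1")
  expect_length(m$models, 0L)
})

test_that("position classification applies the stated precedence", {
  m <- load_annotation(fixture_gff())
  expect_equal(classify_position(m, "chr1", 1200), "exonic")
  expect_equal(classify_position(m, "chr1", 1050), "utr5")
  expect_equal(classify_position(m, "chr1", 1800), "utr3")
  # gA's intron [1401,1600] lies inside gB's upstream window: intron wins
  expect_equal(classify_position(m, "chr1", 1500), "intron")
  # position 50 sits in gA's 1000-nt upstream window (TSS at 1001)
  expect_equal(classify_position(m, "chr1", 50), "upstream")
  # minus-strand gB's window is 3001-4000; between the genes is intergenic
  expect_equal(classify_position(m, "chr1", 3500), "upstream")
  expect_equal(classify_position(m, "chr1", 2100), "intergenic")
  expect_equal(classify_position(m, "chr1", 4500), "intergenic")
  # minus-strand gB: exonic inside its CDS, utr5 at the high end
  expect_equal(classify_position(m, "chr1", 2600), "exonic")
  expect_equal(classify_position(m, "chr1", 2950), "utr5")
  expect_equal(classify_position(m, "chr1", 2450), "utr3")
  expect_error(classify_position(m, "chrX", 10), "unknown sequence_id")
})

test_that("minus-strand 5' UTR lies at higher coordinates than the 3' UTR", {
  m <- load_annotation(fixture_gff())
  gB <- m$models$gB
  expect_gt(min(GenomicRanges::start(gB$utr5)),
            max(GenomicRanges::end(gB$utr3)))
  expect_equal(GenomicRanges::start(gB$upstream), 3001)
})

test_that("tract localization uses majority overlap with precedence ties", {
  m <- load_annotation(fixture_gff())
  tracts <- data.frame(
    sequence_id = "chr1",
    # fully exonic; 60% intron/40% exonic; 50/50 tie; no feature at all
    start = c(1150L, 1360L, 1380L, 4500L),
    end = c(1200L, 1460L, 1420L, 4560L))
  loc <- localize_tracts(tracts, m)
  expect_equal(loc$region_class,
               c("exonic", "intron", "exonic", "intergenic"))
  expect_equal(loc$gene_id, c("gA", "gA", "gA", NA))
  expect_equal(loc$protein_id, c("pA2", "pA2", "pA2", NA))
})

test_that("every position gets exactly one class and counts partition", {
  m <- load_annotation(fixture_gff())
  pos <- seq(1, 3500, by = 13)
  cls <- classify_position(m, "chr1", pos)
  expect_true(all(cls %in% c("exonic", "utr5", "utr3", "intron",
                             "upstream", "intergenic")))
  one_nt <- data.frame(sequence_id = "chr1", start = pos - 1L, end = pos)
  loc <- localize_tracts(one_nt, m)
  expect_equal(loc$region_class, cls)  # 1-nt tracts == position classes
})

test_that("synthetic GFF3 round-trips: CDS slices translate to proteins", {
  sim <- simulate_dataset(small_sim_config(seed = 5))
  dir <- tempfile()
  dir.create(dir)
  writeLines(sim$gff_lines, file.path(dir, "a.gff3"))
  models <- load_annotation(file.path(dir, "a.gff3"))
  expect_length(models$models, sim$config$n_genes)
  genome <- strsplit(paste(sim$genome_bases, collapse = ""), "")[[1L]]
  for (gid in sample(names(sim$cds), 12)) {
    mm <- models$models[[gid]]
    segs <- GenomicRanges::sort(mm$cds)
    s <- paste(unlist(lapply(seq_along(segs), function(k)
      genome[GenomicRanges::start(segs)[k]:GenomicRanges::end(segs)[k]])),
      collapse = "")
    if (mm$strand == "-") s <- revcomp_chr(s)
    expect_equal(translate_codons(s),
                 paste0(sim$proteins[[mm$protein_id]], "*"),
                 info = gid)
  }
})
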