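# Scaled-down simulation configurations for fast tests.

small_homoaa_spec <- function() {
  data.frame(residue = c("Q", "A", "E"),
             theta = c(0.7, 0.2, 0.25),
             tnr_mean = c(13, 9, 10),
             variant_mean = c(8, 9, 9),
             n_tracts = c(40L, 15L, 15L),
             stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 160000L, n_genes = 80L,
               homoaa_spec = small_homoaa_spec(),
               ontology_spec = list(n_terms = 40L, dag_depth = 3L,
                                    enrichment_odds = 5,
                                    base_rate = 0.15),
               ppi_spec = list(mean_degree = 3),
               conservation_spec = list(baseline = 0.8, sd = 0.1))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

translate_codons <- function(dna) {
  ncod <- nchar(dna) %/% 3L
  paste(unname(Biostrings::GENETIC_CODE[
    substring(dna, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))]),
    collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
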