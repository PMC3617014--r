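#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end study: the synthetic dataset
#' configuration (or paths to existing inputs), scan and homo-AA
#' parameters, the upstream window, the significance level, the enrichment
#' background choice and the master seed.
#'
#' @param sim a \code{\link{simulation_config}} describing the dataset to
#'   generate, or \code{NULL} to use \code{inputs} (named paths:
#'   \code{genome}, \code{gff3}, \code{cds}, \code{proteins},
#'   \code{protein_map}, \code{obo}, \code{associations}, \code{ppi},
#'   \code{conservation}).
#' @param inputs named list of input paths when \code{sim} is \code{NULL}.
#' @param scan a \code{\link{scan_params}}.
#' @param homoaa a \code{\link{homoaa_params}}.
#' @param upstream upstream window width, nt.
#' @param alpha significance level.
#' @param enrichment_background \code{"all_homoaa"}, \code{"variant_encoded"}
#'   or \code{"whole_set"}.
#' @param top_k number of top enriched terms in the report.
#' @param seed master seed (overrides \code{sim$seed} when \code{sim} given).
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = simulation_config(), inputs = NULL,
                            scan = scan_params(), homoaa = homoaa_params(),
                            upstream = 1000L, alpha = 0.05,
                            enrichment_background = c("all_homoaa",
                                                      "variant_encoded",
                                                      "whole_set"),
                            top_k = 5L, seed = NULL) {
  enrichment_background <- match.arg(enrichment_background)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, inputs = inputs, scan = scan, homoaa = homoaa,
                 upstream = as.integer(upstream), alpha = alpha,
                 enrichment_background = enrichment_background,
                 top_k = as.integer(top_k),
                 seed = if (!is.null(seed)) as.integer(seed)
                 else if (!is.null(sim)) sim$seed else 1L),
            class = "pipeline_config")
}

read_two_col <- function(path, names_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[seq_along(names_)] <- names_
  d
}

#' Run the end-to-end repeat study
#'
#' Executes all stages in dependency order: (optionally) simulate the
#' dataset, scan the genome for tandem repeat tracts and filter to genuine
#' period-3 repeats, fit the order-2 Markov background and profile unit
#' frequencies, localize tracts to gene regions, scan the proteome for
#' homo-AA tracts and classify their encoding, run the composition /
#' length / PPI / conservation statistics, and test GO term
#' over-representation of TNR-encoded proteins. Every intermediate table
#' is written to \code{out_dir}, along with a parameter log and a plain
#' text summary report.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return An object of class \code{"tnr_report"} with all stage results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg, "\n",
        file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    r <- tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    logline("stage %s: done", name)
    r
  }
  cat("", file = log_path)
  logline("pipeline start; seed %d; alpha %g; background %s",
          config$seed, config$alpha, config$enrichment_background)
  logline("scan params: match %d mismatch %d indel %d min_score %d max_period %d",
          config$scan$match, config$scan$mismatch, config$scan$indel,
          config$scan$min_score, config$scan$max_period)
  logline("homo-AA params: min_run %d min_codon_run %d",
          config$homoaa$min_run_length, config$homoaa$min_same_codon_run)

  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_dataset(config$sim,
                                              file.path(out_dir, "inputs")))
    inputs <- as.list(sim$paths)
  } else {
    inputs <- config$inputs
    sim <- NULL
  }

  genome <- stage("read-genome", as_seq_char(
    Biostrings::readDNAStringSet(inputs$genome)))
  names(genome) <- sub("\\s.*$", "", names(genome))

  tracts_all <- stage("scan-dna", scan_tnr(genome, config$scan))
  tracts3 <- stage("filter-period3",
                   filter_period3(tracts_all, genome, config$scan))
  write_tracts_tsv(tracts_all, file.path(out_dir, "tracts_raw.tsv"))

  bg <- stage("background", fit_markov2(genome))
  write_markov2_tsv(bg, file.path(out_dir, "markov_background.tsv"))
  profile <- stage("unit-profile", unit_frequency_profile(tracts3, bg))
  utils::write.table(profile$profile,
                     file.path(out_dir, "unit_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  models <- stage("load-annotation",
                  load_annotation(inputs$gff3, upstream = config$upstream))
  tracts3 <- stage("localize", localize_tracts(tracts3, models))
  write_tracts_tsv(tracts3, file.path(out_dir, "tracts_period3.tsv"))

  proteins <- stage("read-proteome", {
    p <- Biostrings::readAAStringSet(inputs$proteins)
    names(p) <- sub("\\s.*$", "", names(p))
    as.character(p)
  })
  cds <- stage("read-cds", as_seq_char(
    Biostrings::readDNAStringSet(inputs$cds)))
  names(cds) <- sub("\\s.*$", "", names(cds))
  pmap <- read_two_col(inputs$protein_map, c("protein_id", "gene_id"))
  aat <- stage("scan-protein",
               scan_proteome(proteins, cds, pmap, config$homoaa, models))
  utils::write.table(aat, file.path(out_dir, "homoaa_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- build_protein_sets(aat)

  comp <- stage("stats-composition",
                composition_analysis(aat, sets, config$alpha))
  lens <- stage("stats-length", length_analysis(aat, config$alpha))
  utils::write.table(comp, file.path(out_dir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lens, file.path(out_dir, "lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ppi <- read_two_col(inputs$ppi, c("protein_a", "protein_b"))
  ppi_res <- stage("stats-ppi", ppi_degree_comparison(ppi, sets))
  cons <- utils::read.table(inputs$conservation, sep = "\t",
                            col.names = c("seqid", "start", "end", "score"),
                            stringsAsFactors = FALSE)
  cons_res <- stage("stats-conservation",
                    tract_conservation_comparison(aat, cons))

  ont <- stage("parse-obo", parse_obo(inputs$obo))
  assoc <- read_two_col(inputs$associations, c("gene_id", "term_id"))
  # study/background on protein identifiers via the gene-protein map
  g2p <- stats::setNames(pmap$protein_id, pmap$gene_id)
  assoc_p <- data.frame(gene_id = unname(g2p[assoc$gene_id]),
                        term_id = assoc$term_id, stringsAsFactors = FALSE)
  assoc_p <- assoc_p[!is.na(assoc_p$gene_id), ]
  ann <- stage("propagate", propagate_annotations(ont, assoc_p))
  background <- switch(config$enrichment_background,
                       whole_set = pmap$protein_id,
                       all_homoaa = sets$all,
                       variant_encoded = union(sets$variant, sets$tnr))
  enr <- stage("enrich",
               fisher_overrepresentation(sets$tnr, background, ann, ont))
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  region_counts <- table(factor(tracts3$region_class,
                                levels = REGION_CLASSES))
  report <- structure(list(
    n_tracts_raw = nrow(tracts_all), n_tracts_period3 = nrow(tracts3),
    region_counts = region_counts, unit_profile = profile,
    protein_counts = c(tnr = length(sets$tnr),
                       variant = length(sets$variant),
                       all = length(sets$all)),
    composition = comp, lengths = lens,
    ppi = list(U = ppi_res$U, p_value = ppi_res$p_value),
    conservation = list(U = cons_res$U, p_value = cons_res$p_value),
    enrichment_top = utils::head(enr, config$top_k),
    alpha = config$alpha, seed = config$seed,
    truth = if (!is.null(sim)) list(tracts = sim$truth_tracts,
                                    homoaa = sim$truth_homoaa,
                                    planted_term = sim$planted_term)
    else NULL,
    homoaa_tracts = aat, tracts = tracts3, protein_sets = sets,
    out_dir = out_dir), class = "tnr_report")
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  logline("pipeline done")
  report
}

#' @export
print.tnr_report <- function(x, ...) {
  cat("== Tandem repeat / homo-AA tract study report ==\n")
  cat(sprintf("seed %d, alpha %g\n", x$seed, x$alpha))
  cat(sprintf("\nDNA tracts: %d scanned, %d after period-3 filtering\n",
              x$n_tracts_raw, x$n_tracts_period3))
  cat("region classes:\n")
  for (cl in names(x$region_counts))
    cat(sprintf("  %-10s %d\n", cl, x$region_counts[[cl]]))
  cat(sprintf("\nunit distribution vs background: chi-sq %.1f (df %d), p %.3g\n",
              x$unit_profile$chisq$stat, x$unit_profile$chisq$df,
              x$unit_profile$chisq$p_value))
  cat(sprintf("\nhomo-AA proteins: %d TNR-encoded + %d variant-encoded (union %d)\n",
              x$protein_counts["tnr"], x$protein_counts["variant"],
              x$protein_counts["all"]))
  sig <- x$composition[x$composition$significant, ]
  cat(sprintf("\ncomposition: %d/%d residues significant at alpha:",
              nrow(sig), nrow(x$composition)))
  cat(sprintf(" %s", paste(sprintf("%s(%+.2f)", sig$residue,
                                   sig$log2_proportion_ratio),
                           collapse = " ")), "\n")
  sigl <- x$lengths[!is.na(x$lengths$p_value) & x$lengths$significant, ]
  cat(sprintf("length: %d residues significant:", nrow(sigl)))
  cat(sprintf(" %s", paste(sprintf("%s(%+.2f)", sigl$residue,
                                   sigl$log2_length_ratio),
                           collapse = " ")), "\n")
  cat(sprintf("\nPPI degree comparison: p = %.3g\n", x$ppi$p_value))
  cat(sprintf("conservation comparison: p = %.3g\n",
              x$conservation$p_value))
  cat("\ntop enriched terms (study = TNR-encoded proteins):\n")
  e <- x$enrichment_top
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s  E=%.3g  (%d/%d study, %d/%d bg)  %s\n",
                e$term_id[i], e$e_value[i], e$study_with[i],
                e$study_with[i] + e$study_without[i], e$bg_with[i],
                e$bg_with[i] + e$bg_without[i], e$term_name[i]))
  invisible(x)
}
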