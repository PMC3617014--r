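# ---- synthetic data generator -------------------------------------------
# All generator stages draw from R's RNG seeded deterministically from
# config$seed (one derived seed per stage), so a config fully determines
# every emitted byte.

codons_by_aa <- function() {
  gc_ <- GENCODE
  split(names(gc_), unname(gc_))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

default_planted_tnrs <- function() {
  data.frame(
    unit = c("CAG", "CTG", "AAT", "GCC", "ACT",
             "CAG", "CTG", "CGG", "CAG", "CAG", "CAG", "GCA"),
    copies = c(20L, 15L, 12L, 14L, 10L, 12L, 10L, 10L, 9L, 15L, 10L, 8L),
    mismatches = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    region_class = c(rep("intergenic", 5L), "intron", "intron", "utr5",
                     "utr3", "upstream", "exonic", "exonic"),
    stringsAsFactors = FALSE)
}

default_homoaa_spec <- function() {
  data.frame(
    residue = c("Q", "A", "E", "N", "S", "P"),
    theta = c(0.7, 0.2, 0.25, 0.25, 0.2, 0.1),
    tnr_mean = c(13, 9, 10, 10, 9, 9),
    variant_mean = c(8, 9, 9, 9, 9, 10),
    n_tracts = c(150L, 60L, 60L, 60L, 60L, 40L),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic study dataset
#'
#' Describes every input the generator emits: an order-2 Markov genomic
#' background with planted tandem repeat tracts, gene models with spliced
#' CDS on both strands, proteins with planted homo-AA runs whose codon
#' usage follows per-residue TNR-/variant-encoding proportions and 7-shifted
#' geometric length distributions, an ontology DAG with one term planted at
#' chosen enrichment odds in repeat-carrying genes, protein interaction
#' pairs, and a per-base conservation track over the CDS.
#'
#' @param seed integer master seed; fully determines every output byte.
#' @param genome_length genome length in nucleotides.
#' @param markov_spec \code{"uniform"}, a \code{"markov2"} object, or a
#'   list with \code{cond_prob} (16 x 4) and \code{dinuc_freq} (16).
#' @param planted_tnrs data frame \code{unit}, \code{copies},
#'   \code{mismatches}, \code{region_class} (one of exonic, intron, utr5,
#'   utr3, upstream, intergenic).
#' @param n_genes number of gene models.
#' @param homoaa_spec data frame \code{residue}, \code{theta} (probability
#'   a planted run is TNR-encoded), \code{tnr_mean}, \code{variant_mean}
#'   (mean run lengths, residues, both >= 7), \code{n_tracts}.
#' @param ontology_spec list: \code{n_terms}, \code{dag_depth},
#'   \code{enrichment_odds}, \code{base_rate}.
#' @param ppi_spec list: \code{mean_degree} (Poisson mean).
#' @param conservation_spec list: \code{baseline}, \code{sd} (per-base
#'   scores, clipped to [0, 1]).
#' @return An object of class \code{"sim_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 600000L,
                              markov_spec = "uniform",
                              planted_tnrs = default_planted_tnrs(),
                              n_genes = 400L,
                              homoaa_spec = default_homoaa_spec(),
                              ontology_spec = list(n_terms = 60L,
                                                   dag_depth = 4L,
                                                   enrichment_odds = 5,
                                                   base_rate = 0.15),
                              ppi_spec = list(mean_degree = 4),
                              conservation_spec = list(baseline = 0.8,
                                                       sd = 0.1)) {
  if (any(homoaa_spec$theta < 0 | homoaa_spec$theta > 1))
    stop("all theta must lie in [0, 1]")
  if (any(homoaa_spec$tnr_mean < 7 | homoaa_spec$variant_mean < 7))
    stop("mean run lengths must be >= 7 residues")
  single_codon <- c("M", "W")
  bad <- homoaa_spec$residue %in% single_codon & homoaa_spec$theta < 1
  if (any(bad))
    stop("variant encoding impossible for single-codon residue(s): ",
         paste(homoaa_spec$residue[bad], collapse = ", "))
  if (!all(planted_tnrs$region_class %in% REGION_CLASSES))
    stop("unknown region_class in planted_tnrs")
  exonic <- planted_tnrs$region_class == "exonic"
  if (any(exonic & toupper(planted_tnrs$unit) %in% STOP_CODONS))
    stop("exonic planted unit must not be a stop codon")
  if (any(exonic & planted_tnrs$copies < 3L))
    stop("exonic planted tracts need >= 3 copies")
  if (ontology_spec$dag_depth < 1L) stop("dag_depth must be >= 1")
  total_runs <- sum(homoaa_spec$n_tracts)
  dedicated <- sum(planted_tnrs$region_class != "intergenic")
  if (n_genes < dedicated + n_carriers_needed(total_runs))
    stop("n_genes too small for the requested runs and planted tracts")
  cfg <- structure(list(seed = as.integer(seed),
                        genome_length = as.integer(genome_length),
                        markov_spec = markov_spec,
                        planted_tnrs = planted_tnrs,
                        n_genes = as.integer(n_genes),
                        homoaa_spec = homoaa_spec,
                        ontology_spec = ontology_spec,
                        ppi_spec = ppi_spec,
                        conservation_spec = conservation_spec),
                   class = "sim_config")
  cfg
}

# ~15% of carrier proteins hold two runs (real homo-AA proteomes average
# ~1.1-1.2 tracts per protein); the rest hold one
n_carriers_needed <- function(total_runs) {
  total_runs - floor(0.15 * total_runs)
}

sim_markov_model <- function(spec) {
  if (inherits(spec, "markov2")) return(spec)
  if (identical(spec, "uniform")) return(uniform_markov2())
  if (is.list(spec) && !is.null(spec$cond_prob)) {
    m <- uniform_markov2()
    m$cond_prob[] <- spec$cond_prob
    if (!is.null(spec$dinuc_freq)) m$dinuc_freq[] <- spec$dinuc_freq
    return(m)
  }
  stop("markov_spec must be 'uniform', a markov2 model, or a list")
}

bg_draw <- function(model, n) {
  if (n <= 0L) return(character(0))
  c(DNA_BASES4, "N")[C_markov2_sample(as.integer(n), model$cond_prob,
                                      as.numeric(model$dinuc_freq)) + 1L]
}

# tract base vector with `mismatches` substitutions in interior units
tract_bases <- function(unit, copies, mismatches) {
  u <- strsplit(unit, "")[[1L]]
  p <- length(u)
  v <- rep(u, copies)
  len <- p * copies
  if (mismatches > 0L) {
    cand <- (p + 1L):(len - p)  # keep first and last unit pure
    pos <- sample(cand, mismatches)
    for (q in pos) v[q] <- sample(setdiff(DNA_BASES4, v[q]), 1L)
  }
  v
}

# surround a tract with background, breaking the repeat phase two bases
# deep on each side so the planted boundaries are score-maximal
embed_tract <- function(unit, copies, mismatches, model, pad_left, pad_right) {
  u <- strsplit(unit, "")[[1L]]
  p <- length(u)
  left <- bg_draw(model, pad_left)
  right <- bg_draw(model, pad_right)
  fix <- function(vec, idx, forbidden) {
    if (idx >= 1L && idx <= length(vec) && vec[idx] == forbidden)
      vec[idx] <- sample(setdiff(DNA_BASES4, forbidden), 1L)
    vec
  }
  nl <- length(left)
  left <- fix(left, nl, u[p])        # base expected to precede phase 0
  left <- fix(left, nl - 1L, u[p - 1L])
  len <- p * copies
  right <- fix(right, 1L, u[(len %% p) + 1L])
  right <- fix(right, 2L, u[((len + 1L) %% p) + 1L])
  list(bases = c(left, tract_bases(unit, copies, mismatches), right),
       tract_offset = length(left), tract_len = len)
}

shifted_geom_len <- function(n, mean_len) {
  if (mean_len <= 7) return(rep(7L, n))
  7L + stats::rgeom(n, prob = 1 / (mean_len - 6))
}

variant_codon_run <- function(residue, len, cods) {
  v <- character(len)
  last <- ""
  runl <- 0L
  for (i in seq_len(len)) {
    choice <- if (runl >= 6L) setdiff(cods, last) else cods
    v[i] <- if (length(choice) == 1L) choice else sample(choice, 1L)
    if (v[i] == last) runl <- runl + 1L else { last <- v[i]; runl <- 1L }
  }
  v
}

# random sense codon whose amino acid differs from `aa_not`, with optional
# base constraints (position -> forbidden base) to break repeat phase
flank_codon <- function(aa_not, forbid = NULL, cods_aa) {
  sense <- setdiff(names(GENCODE),
                   c(STOP_CODONS, cods_aa[[aa_not]] %||% character(0)))
  for (i in seq_len(200L)) {
    cd <- sample(sense, 1L)
    ok <- TRUE
    if (!is.null(forbid))
      for (pos in names(forbid))
        if (substr(cd, as.integer(pos), as.integer(pos)) ==
            forbid[[pos]]) { ok <- FALSE; break }
    if (ok) return(cd)
  }
  sample(sense, 1L)  # constraints relaxed (practically unreachable)
}

#' Generate the genomic background with planted non-genic repeat tracts
#'
#' Stage 1 of the generator: draws the genome from the order-2 Markov
#' background and plants the non-genic (intergenic-class) tracts of
#' \code{planted_tnrs} in a dedicated tail region of the genome, each with
#' the requested unit, copy number and mismatch count, non-overlapping and
#' separated by generous spacers, with the repeat phase broken two bases
#' deep at both boundaries. Genic-class tracts are planted later by
#' \code{\link{generate_gene_models}}, which must build the gene structure
#' first.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A \code{"tnr_sim"} state: \code{genome_bases} (character
#'   vector), \code{truth_tracts}, layout bookkeeping.
#' @export
generate_genome <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  model <- sim_markov_model(config$markov_spec)
  L <- config$genome_length
  bases <- bg_draw(model, L)
  inter <- config$planted_tnrs[config$planted_tnrs$region_class ==
                                 "intergenic", , drop = FALSE]
  # reserve the first ~72% of the genome for genes, the tail for
  # intergenic tracts (keeps them out of every upstream window)
  gene_region_end <- floor(L * 0.72)
  cursor <- gene_region_end + 2000L
  truth <- list()
  if (nrow(inter) > 0L) for (i in seq_len(nrow(inter))) {
    u <- toupper(inter$unit[i])
    emb <- embed_tract(u, inter$copies[i], inter$mismatches[i], model, 2L, 2L)
    s0 <- cursor + emb$tract_offset          # 0-based tract start
    e0 <- s0 + emb$tract_len
    if (e0 + 200L > L)
      stop("planted footprint exceeds genome_length (sizing error)")
    bases[(cursor + 1L):(cursor + length(emb$bases))] <- emb$bases
    truth[[length(truth) + 1L]] <- data.frame(
      sequence_id = "chr1", start = s0, end = e0, unit = u,
      canonical_unit = canonical_unit(u), copies = inter$copies[i],
      mismatches = inter$mismatches[i], region_class = "intergenic",
      gene_id = NA_character_, stringsAsFactors = FALSE)
    cursor <- cursor + length(emb$bases) + 50L + sample(50:250, 1L)
  }
  structure(list(config = config, model = model, genome_bases = bases,
                 gene_region_end = gene_region_end,
                 truth_tracts = do.call(rbind, truth)),
            class = "tnr_sim")
}

# assemble one gene; returns a list describing the genomic block
build_gene <- function(gid, tid, pid, strand, runs, exonic_tract,
                       genic_tract, model, cods_aa) {
  # --- coding part, in codons ------------------------------------------
  run_lens <- if (nrow(runs)) runs$length else integer(0)
  body_n <- 80L + sum(run_lens) +
    (if (!is.null(exonic_tract)) exonic_tract$copies else 0L)
  body_aa <- sample(AA_STANDARD, body_n, replace = TRUE)
  body <- vapply(body_aa, function(a) {
    cd <- cods_aa[[a]]
    if (length(cd) == 1L) cd else sample(cd, 1L)
  }, "", USE.NAMES = FALSE)
  items <- list()
  if (nrow(runs)) for (j in seq_len(nrow(runs)))
    items[[length(items) + 1L]] <- list(kind = runs$class[j],
                                        residue = runs$residue[j],
                                        len = runs$length[j])
  if (!is.null(exonic_tract))
    items[[length(items) + 1L]] <- list(kind = "exonic_tnr",
                                        unit = exonic_tract$unit,
                                        len = exonic_tract$copies,
                                        mismatches = 0L)
  truth_runs <- list()
  exonic_span <- NULL
  if (length(items)) {
    totlen <- sum(vapply(items, `[[`, 0L, "len"))
    gap <- max(12L, (body_n - totlen) %/% (length(items) + 1L))
    pos <- gap
    for (it in items) {
      a <- pos                             # 0-based codon index in body
      b <- a + it$len
      if (it$kind == "exonic_tnr") {
        u <- toupper(it$unit)
        res <- unname(GENCODE[u])
        body[(a + 1L):b] <- u
        exonic_span <- c(a, b, u)
      } else {
        res <- it$residue
        cd <- cods_aa[[res]]
        body[(a + 1L):b] <- if (it$kind == "tnr")
          rep(if (length(cd) == 1L) cd else sample(cd, 1L), it$len)
        else variant_codon_run(res, it$len, cd)
      }
      codon0 <- body[a + 1L]
      uvec <- strsplit(codon0, "")[[1L]]
      # flanks: different residue; break the repeat phase two bases deep
      if (a >= 1L)
        body[a] <- flank_codon(res, list("3" = uvec[3L], "2" = uvec[2L]),
                               cods_aa)
      if (b < body_n)
        body[b + 1L] <- flank_codon(res, list("1" = uvec[1L],
                                              "2" = uvec[2L]), cods_aa)
      if (it$kind != "exonic_tnr")
        truth_runs[[length(truth_runs) + 1L]] <- data.frame(
          protein_id = pid, gene_id = gid, residue = res,
          start = a + 1L, end = b + 1L, length = it$len,   # +1: start codon
          encoding_class = if (it$kind == "tnr") "tnr" else "variant",
          stringsAsFactors = FALSE)
      pos <- b + gap
    }
    if (!is.null(exonic_span)) {
      u <- exonic_span[3L]
      truth_runs[[length(truth_runs) + 1L]] <- data.frame(
        protein_id = pid, gene_id = gid,
        residue = unname(GENCODE[u]),
        start = as.integer(exonic_span[1L]) + 1L,
        end = as.integer(exonic_span[2L]) + 1L,
        len = as.integer(exonic_span[2L]) - as.integer(exonic_span[1L]),
        encoding_class = "tnr", stringsAsFactors = FALSE)
      names(truth_runs[[length(truth_runs)]])[6L] <- "length"
    }
  }
  codons <- c("ATG", body, sample(STOP_CODONS, 1L))
  # repair accidental homo-AA runs outside the planted spans
  planted_spans <- if (length(truth_runs))
    do.call(rbind, truth_runs)[, c("start", "end")] else NULL
  for (pass in 1:10) {
    aa <- unname(GENCODE[codons])
    prot <- paste(aa[-length(aa)], collapse = "")
    found <- find_homoaa_runs(prot, homoaa_params(7L, 7L))
    extra <- found
    if (!is.null(planted_spans) && nrow(found))
      extra <- found[!(found$start %in% planted_spans$start &
                         found$end %in% planted_spans$end), , drop = FALSE]
    if (nrow(extra) == 0L) break
    for (j in seq_len(nrow(extra))) {
      mid <- extra$start[j] + extra$length[j] %/% 2L  # codon index (0-based + ATG)
      codons[mid + 1L] <- flank_codon(extra$residue[j], NULL, cods_aa)
    }
  }
  cds <- paste(codons, collapse = "")
  cds_len <- nchar(cds)
  prot <- paste(unname(GENCODE[codons[-length(codons)]]),
                collapse = "")

  # --- transcript segments ---------------------------------------------
  mk_utr <- function(with_tract) {
    if (is.null(with_tract)) return(list(bases = bg_draw(model,
                                                         sample(40:80, 1L)),
                                         tract = NULL))
    emb <- embed_tract(toupper(with_tract$unit), with_tract$copies,
                       with_tract$mismatches, model, 20L, 20L)
    list(bases = emb$bases,
         tract = c(emb$tract_offset, emb$tract_len, toupper(with_tract$unit),
                   with_tract$copies, with_tract$mismatches))
  }
  gt_class <- if (!is.null(genic_tract)) genic_tract$region_class else ""
  u5 <- mk_utr(if (gt_class == "utr5") genic_tract else NULL)
  u3 <- mk_utr(if (gt_class == "utr3") genic_tract else NULL)
  if (gt_class == "intron") {
    emb <- embed_tract(toupper(genic_tract$unit), genic_tract$copies,
                       genic_tract$mismatches, model, 40L, 40L)
    intron <- list(bases = emb$bases,
                   tract = c(emb$tract_offset, emb$tract_len,
                             toupper(genic_tract$unit), genic_tract$copies,
                             genic_tract$mismatches))
  } else {
    intron <- list(bases = bg_draw(model, sample(60:120, 1L)), tract = NULL)
  }
  # splice site inside the CDS at an arbitrary nucleotide
  split_at <- sample(seq(floor(cds_len * 0.3), ceiling(cds_len * 0.7)), 1L)
  cds_bases <- strsplit(cds, "")[[1L]]
  segs <- list(
    list(type = "utr5", bases = u5$bases, tract = u5$tract),
    list(type = "cds", bases = cds_bases[seq_len(split_at)], tract = NULL),
    list(type = "intron", bases = intron$bases, tract = intron$tract),
    list(type = "cds", bases = cds_bases[(split_at + 1L):cds_len],
         tract = NULL),
    list(type = "utr3", bases = u3$bases, tract = u3$tract))
  list(gene_id = gid, mrna_id = tid, protein_id = pid, strand = strand,
       segs = segs, cds = cds, protein = prot,
       truth_runs = if (length(truth_runs)) do.call(rbind, truth_runs)
       else NULL,
       exonic_span = exonic_span, split_at = split_at,
       exonic_tract = exonic_tract)
}

#' Generate gene models, CDS, proteins and genic planted tracts
#'
#' Stage 2: builds \code{n_genes} non-overlapping spliced gene models on
#' both strands (5'UTR, two CDS exons split at an arbitrary nucleotide, one
#' intron, 3'UTR), writes them into the genome, and emits the GFF3 lines,
#' CDS and protein sequences and the protein-gene map. Planted homo-AA runs
#' follow \code{homoaa_spec}: each run is TNR-encoded (one codon repeated)
#' with probability theta, else variant-encoded with the same-codon run
#' capped at 6; run lengths are 7-shifted geometric. Genic-class planted
#' tracts (exonic, intron, utr5, utr3, upstream) are embedded in dedicated
#' genes; exonic ones are frame-aligned codon repeats and therefore also
#' recorded as TNR-encoded homo-AA runs.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param sim state from \code{\link{generate_genome}}.
#' @return The state, extended with \code{gff_lines}, \code{cds},
#'   \code{proteins}, \code{protein_map}, \code{truth_homoaa} and the
#'   genic rows of \code{truth_tracts}.
#' @export
generate_gene_models <- function(config, sim) {
  set.seed(derive_seed(config$seed, 2L))
  model <- sim$model
  cods_aa <- codons_by_aa()
  spec <- config$homoaa_spec
  # planted homo-AA run roster
  runs <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n_tracts[i]
    if (n == 0L) return(NULL)
    cls <- ifelse(stats::runif(n) < spec$theta[i], "tnr", "variant")
    len <- ifelse(cls == "tnr",
                  shifted_geom_len(n, spec$tnr_mean[i]),
                  shifted_geom_len(n, spec$variant_mean[i]))
    data.frame(residue = spec$residue[i], class = cls,
               length = as.integer(len), stringsAsFactors = FALSE)
  }))
  if (is.null(runs)) runs <- data.frame(residue = character(0),
                                        class = character(0),
                                        length = integer(0))
  runs <- runs[sample.int(nrow(runs)), , drop = FALSE]
  genic <- config$planted_tnrs[!config$planted_tnrs$region_class %in%
                                 c("intergenic"), , drop = FALSE]
  n_dedicated <- nrow(genic)
  n_carrier <- n_carriers_needed(nrow(runs))
  n_two <- nrow(runs) - n_carrier   # carriers holding two runs
  if (config$n_genes < n_dedicated + n_carrier)
    stop("n_genes too small")  # guarded at config time as well
  # assignment: dedicated genes first, then two-run carriers, then one-run
  gene_runs <- vector("list", config$n_genes)
  ri <- 1L
  for (g in seq_len(n_carrier)) {
    take <- if (g <= n_two) 2L else 1L
    take <- min(take, nrow(runs) - ri + 1L)
    if (take <= 0L) break
    gene_runs[[n_dedicated + g]] <- runs[ri:(ri + take - 1L), , drop = FALSE]
    ri <- ri + take
  }
  empty_runs <- runs[0L, , drop = FALSE]
  genes <- vector("list", config$n_genes)
  cursor <- 1000L
  gff <- c("##gff-version 3",
           sprintf("##sequence-region chr1 1 %d", config$genome_length))
  truth_tracts <- list()
  truth_runs <- list()
  cds_out <- character(config$n_genes)
  prot_out <- character(config$n_genes)
  gids <- sprintf("G%04d", seq_len(config$n_genes))
  tids <- sprintf("T%04d", seq_len(config$n_genes))
  pids <- sprintf("P%04d", seq_len(config$n_genes))
  bases <- sim$genome_bases
  for (g in seq_len(config$n_genes)) {
    strand <- sample(c("+", "-"), 1L)
    gt <- if (g <= n_dedicated) genic[g, , drop = FALSE] else NULL
    exonic_tract <- NULL
    genic_tract <- NULL
    upstream_tract <- NULL
    if (!is.null(gt)) {
      if (gt$region_class == "exonic") exonic_tract <- gt
      else if (gt$region_class == "upstream") upstream_tract <- gt
      else genic_tract <- gt
    }
    gr <- gene_runs[[g]] %||% empty_runs
    gb <- build_gene(gids[g], tids[g], pids[g], strand, gr, exonic_tract,
                     genic_tract, model, cods_aa)
    # ---- genomic placement -------------------------------------------
    seg_lens <- vapply(gb$segs, function(s) length(s$bases), 0L)
    core_len <- sum(seg_lens)
    pre <- list(bases = character(0), tract_offset = NULL)
    post <- list(bases = character(0), tract_offset = NULL)
    if (!is.null(upstream_tract)) {
      emb <- embed_tract(toupper(upstream_tract$unit),
                         upstream_tract$copies, upstream_tract$mismatches,
                         model, 100L, 120L)
      if (strand == "+") pre <- emb else post <- emb
    }
    pre_len <- length(pre$bases)
    post_len <- length(post$bases)
    block_len <- pre_len + core_len + post_len
    if (cursor + block_len + 200L > sim$gene_region_end)
      stop("gene region exhausted; increase genome_length (sizing error)")
    core_off <- cursor + pre_len          # 0-based offset of gene start
    # transcript-orientation offsets of segments
    toff <- cumsum(c(0L, seg_lens))[seq_along(seg_lens)]
    # genomic offset (within core) of transcript interval [t0, t1)
    g_int <- function(t0, t1) {
      if (strand == "+") c(t0, t1) else c(core_len - t1, core_len - t0)
    }
    # write block into the genome
    core_seq <- unlist(lapply(gb$segs, `[[`, "bases"), use.names = FALSE)
    if (strand == "-")
      core_seq <- rev(c(T = "A", A = "T", C = "G", G = "C",
                        N = "N")[core_seq])
    block <- c(pre$bases, core_seq, post$bases)
    bases[(cursor + 1L):(cursor + block_len)] <- block
    # ---- truth: upstream / genic tracts -------------------------------
    rc_unit <- function(u) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(u)))
    note_tract <- function(s0, e0, unit, copies, mism, cls) {
      fw_unit <- if (strand == "-" && cls != "upstream") rc_unit(unit)
      else unit
      truth_tracts[[length(truth_tracts) + 1L]] <<- data.frame(
        sequence_id = "chr1", start = s0, end = e0, unit = fw_unit,
        canonical_unit = canonical_unit(fw_unit), copies = copies,
        mismatches = mism, region_class = cls, gene_id = gids[g],
        stringsAsFactors = FALSE)
    }
    if (!is.null(pre$tract_offset))
      note_tract(cursor + pre$tract_offset,
                 cursor + pre$tract_offset + pre$tract_len,
                 toupper(upstream_tract$unit), upstream_tract$copies,
                 upstream_tract$mismatches, "upstream")
    if (!is.null(post$tract_offset))
      note_tract(cursor + pre_len + core_len + post$tract_offset,
                 cursor + pre_len + core_len + post$tract_offset +
                   post$tract_len,
                 toupper(upstream_tract$unit), upstream_tract$copies,
                 upstream_tract$mismatches, "upstream")
    for (si in seq_along(gb$segs)) {
      tr <- gb$segs[[si]]$tract
      if (is.null(tr)) next
      t0 <- toff[si] + as.integer(tr[1L])
      t1 <- t0 + as.integer(tr[2L])
      gi <- g_int(t0, t1)
      note_tract(core_off + gi[1L], core_off + gi[2L], tr[3L],
                 as.integer(tr[4L]), as.integer(tr[5L]),
                 gb$segs[[si]]$type |>
                   switch(utr5 = "utr5", utr3 = "utr3", intron = "intron"))
    }
    if (!is.null(gb$exonic_span)) {
      # codon span -> CDS nt span -> genomic (single gene-level record)
      a <- as.integer(gb$exonic_span[1L]) + 1L  # + start codon
      b <- as.integer(gb$exonic_span[2L]) + 1L
      nt0 <- 3L * a; nt1 <- 3L * b
      # CDS occupies transcript offsets [u5, u5+split) and
      # [u5+split+intron, ...): map the nt span through the intron
      u5len <- seg_lens[1L]; split <- gb$split_at; ilen <- seg_lens[3L]
      tr_nt <- function(nt) if (nt <= split) u5len + nt
      else u5len + ilen + nt
      pieces <- list()
      if (nt0 < split && nt1 > split) {
        pieces[[1]] <- c(tr_nt(nt0), u5len + split)
        pieces[[2]] <- c(u5len + split + ilen, tr_nt(nt1))
      } else pieces[[1]] <- c(tr_nt(nt0), tr_nt(nt1))
      for (pc in pieces) {
        gi <- g_int(pc[1L], pc[2L])
        note_tract(core_off + gi[1L], core_off + gi[2L],
                   gb$exonic_span[3L],
                   (pc[2L] - pc[1L]) / 3, 0L, "exonic")
      }
    }
    if (!is.null(gb$truth_runs))
      truth_runs[[length(truth_runs) + 1L]] <- gb$truth_runs
    # ---- GFF3 ---------------------------------------------------------
    gline <- function(type, t0, t1, phase, attrs) {
      gi <- g_int(t0, t1)
      sprintf("chr1\ttnrscan_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              type, core_off + gi[1L] + 1L, core_off + gi[2L], strand,
              phase, attrs)
    }
    u5len <- seg_lens[1L]; c1 <- seg_lens[2L]; ilen <- seg_lens[3L]
    c2 <- seg_lens[4L]; u3len <- seg_lens[5L]
    gff <- c(gff,
      gline("gene", 0L, core_len, ".", sprintf("ID=%s;Name=%s", gids[g],
                                               gids[g])),
      gline("mRNA", 0L, core_len, ".",
            sprintf("ID=%s;Parent=%s;protein_id=%s", tids[g], gids[g],
                    pids[g])),
      gline("exon", 0L, u5len + c1, ".",
            sprintf("ID=%s.e1;Parent=%s", tids[g], tids[g])),
      gline("exon", u5len + c1 + ilen, core_len, ".",
            sprintf("ID=%s.e2;Parent=%s", tids[g], tids[g])),
      gline("five_prime_UTR", 0L, u5len, ".",
            sprintf("ID=%s.u5;Parent=%s", tids[g], tids[g])),
      gline("CDS", u5len, u5len + c1, "0",
            sprintf("ID=%s.c1;Parent=%s", tids[g], tids[g])),
      gline("CDS", u5len + c1 + ilen, u5len + c1 + ilen + c2,
            sprintf("%d", (3L - c1 %% 3L) %% 3L),
            sprintf("ID=%s.c2;Parent=%s", tids[g], tids[g])),
      gline("three_prime_UTR", core_len - u3len, core_len, ".",
            sprintf("ID=%s.u3;Parent=%s", tids[g], tids[g])))
    cds_out[g] <- gb$cds
    prot_out[g] <- gb$protein
    genes[[g]] <- list(gene_id = gids[g], strand = strand,
                       start0 = core_off, end0 = core_off + core_len)
    cursor <- cursor + block_len + sample(150:400, 1L)
  }
  sim$genome_bases <- bases
  sim$gff_lines <- gff
  sim$cds <- stats::setNames(cds_out, gids)
  sim$proteins <- stats::setNames(prot_out, pids)
  sim$protein_map <- data.frame(protein_id = pids, gene_id = gids,
                                stringsAsFactors = FALSE)
  sim$truth_homoaa <- do.call(rbind, truth_runs)
  sim$truth_tracts <- rbind(sim$truth_tracts, do.call(rbind, truth_tracts))
  sim$gene_layout <- do.call(rbind, lapply(genes, as.data.frame))
  sim
}

#' Generate an ontology DAG and gene-term associations with planted signal
#'
#' Stage 3: emits an OBO-format DAG (is_a and part_of edges, single root)
#' of \code{n_terms} terms over \code{dag_depth} levels, and a gene-term
#' association table in which one planted term is assigned to
#' TNR-run-carrying genes at odds \code{enrichment_odds} relative to all
#' other genes; every other term is assigned independently of repeat
#' status.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param sim state from \code{\link{generate_gene_models}}.
#' @return The state, extended with \code{obo_lines}, \code{associations},
#'   \code{planted_term}.
#' @export
generate_ontology_and_associations <- function(config, sim) {
  set.seed(derive_seed(config$seed, 3L))
  os <- config$ontology_spec
  n <- as.integer(os$n_terms)
  depth <- as.integer(os$dag_depth)
  ids <- sprintf("GO:%07d", seq_len(n))
  level <- c(0L, sort(sample(rep(seq_len(depth), length.out = n - 1L))))
  edges <- list()
  for (i in seq_len(n)[-1L]) {
    parents_pool <- which(level == level[i] - 1L)
    if (!length(parents_pool)) parents_pool <- which(level < level[i])
    p1 <- if (length(parents_pool) == 1L) parents_pool
    else sample(parents_pool, 1L)
    edges[[length(edges) + 1L]] <- c(i, p1,
                                     if (stats::runif(1) < 0.8) "is_a"
                                     else "part_of")
    if (stats::runif(1) < 0.2 && length(parents_pool) > 1L) {
      p2 <- sample(setdiff(parents_pool, p1), 1L)
      edges[[length(edges) + 1L]] <- c(i, p2, "part_of")
    }
  }
  deepest <- which(level == max(level))
  planted <- ids[deepest[length(deepest)]]
  obo <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    obo <- c(obo, "[Term]", sprintf("id: %s", ids[i]),
             sprintf("name: synthetic term %d", i))
    for (e in edges) if (e[1L] == i) {
      if (e[3L] == "is_a")
        obo <- c(obo, sprintf("is_a: %s ! %s", ids[as.integer(e[2L])],
                              sprintf("synthetic term %s", e[2L])))
      else
        obo <- c(obo, sprintf("relationship: part_of %s ! %s",
                              ids[as.integer(e[2L])],
                              sprintf("synthetic term %s", e[2L])))
    }
    obo <- c(obo, "")
  }
  genes <- sim$protein_map$gene_id
  tnr_genes <- unique(sim$truth_homoaa$gene_id[
    sim$truth_homoaa$encoding_class == "tnr"])
  p_base <- os$base_rate %||% 0.15
  odds <- os$enrichment_odds * p_base / (1 - p_base)
  p_repeat <- odds / (1 + odds)
  assoc <- list()
  for (t in ids) {
    if (t == planted) {
      pr <- ifelse(genes %in% tnr_genes, p_repeat, p_base)
    } else {
      pr <- rep(stats::runif(1, 0.02, 0.25), length(genes))
    }
    hit <- stats::runif(length(genes)) < pr
    if (any(hit))
      assoc[[length(assoc) + 1L]] <- data.frame(gene_id = genes[hit],
                                                term_id = t,
                                                stringsAsFactors = FALSE)
  }
  sim$obo_lines <- obo
  sim$associations <- do.call(rbind, assoc)
  sim$planted_term <- planted
  sim
}

#' Generate protein interaction pairs and a conservation track
#'
#' Stage 4: draws per-protein degrees from a Poisson distribution and wires
#' an undirected interaction list by stub matching (self-pairs and
#' duplicates removed; degree parameter 0 gives an empty list), and emits a
#' per-base conservation score track covering every CDS base, normal around
#' the configured baseline and clipped to [0, 1] — both generated
#' identically for TNR- and variant-encoded proteins.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param sim state from \code{\link{generate_gene_models}}.
#' @return The state, extended with \code{ppi} and \code{conservation}.
#' @export
generate_ppi_and_conservation <- function(config, sim) {
  set.seed(derive_seed(config$seed, 4L))
  prots <- sim$protein_map$protein_id
  lambda <- config$ppi_spec$mean_degree %||% 0
  ppi <- data.frame(protein_a = character(0), protein_b = character(0),
                    stringsAsFactors = FALSE)
  if (lambda > 0) {
    deg <- stats::rpois(length(prots), lambda)
    stubs <- rep(prots, deg)
    if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
    stubs <- sample(stubs)
    if (length(stubs) >= 2L) {
      a <- stubs[seq(1L, length(stubs), by = 2L)]
      b <- stubs[seq(2L, length(stubs), by = 2L)]
      keep <- a != b
      lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
      d <- unique(data.frame(protein_a = lo, protein_b = hi,
                             stringsAsFactors = FALSE))
      ppi <- d[order(d$protein_a, d$protein_b), , drop = FALSE]
      rownames(ppi) <- NULL
    }
  }
  cs <- config$conservation_spec
  gl <- sim$gene_layout
  cons <- list()
  # per-base scores over gene CDS spans (gene bodies cover the CDS)
  for (i in seq_len(nrow(gl))) {
    s0 <- gl$start0[i]; e0 <- gl$end0[i]
    sc <- pmin(1, pmax(0, stats::rnorm(e0 - s0, cs$baseline, cs$sd)))
    r <- rle(sc)
    ends <- s0 + cumsum(r$lengths)
    starts <- ends - r$lengths
    cons[[i]] <- data.frame(seqid = "chr1", start = starts, end = ends,
                            score = r$values, stringsAsFactors = FALSE)
  }
  sim$ppi <- ppi
  sim$conservation <- do.call(rbind, cons)
  sim
}

#' Generate a complete synthetic study dataset
#'
#' Runs all generator stages (\code{\link{generate_genome}},
#' \code{\link{generate_gene_models}},
#' \code{\link{generate_ontology_and_associations}},
#' \code{\link{generate_ppi_and_conservation}}) and optionally writes the
#' standard-format files: genome/CDS/protein FASTA, GFF3, OBO, association,
#' PPI and truth TSVs, and a bedGraph conservation track.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir optional output directory; created if missing.
#' @return A \code{"tnr_sim"} object; when \code{dir} is given, a
#'   \code{paths} element lists the written files.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  sim <- generate_genome(config)
  sim <- generate_gene_models(config, sim)
  sim <- generate_ontology_and_associations(config, sim)
  sim <- generate_ppi_and_conservation(config, sim)
  sim$genome <- c(chr1 = paste(sim$genome_bases, collapse = ""))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pth <- function(f) file.path(dir, f)
    write_fasta(sim$genome, pth("genome.fasta"))
    write_fasta(sim$cds, pth("cds.fasta"))
    write_fasta(sim$proteins, pth("proteins.fasta"))
    writeLines(sim$gff_lines, pth("annotation.gff3"))
    writeLines(sim$obo_lines, pth("ontology.obo"))
    wtsv <- function(x, f) utils::write.table(x, pth(f), sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE)
    wtsv(sim$protein_map, "protein_map.tsv")
    wtsv(sim$associations, "associations.tsv")
    wtsv(sim$ppi, "ppi.tsv")
    wtsv(sim$truth_tracts, "truth_tracts.tsv")
    wtsv(sim$truth_homoaa, "truth_homoaa.tsv")
    utils::write.table(sim$conservation, pth("conservation.bedgraph"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    writeLines(sim$planted_term, pth("planted_term.txt"))
    sim$paths <- stats::setNames(
      file.path(dir, c("genome.fasta", "cds.fasta", "proteins.fasta",
                       "annotation.gff3", "ontology.obo", "protein_map.tsv",
                       "associations.tsv", "ppi.tsv", "truth_tracts.tsv",
                       "truth_homoaa.tsv", "conservation.bedgraph",
                       "planted_term.txt")),
      c("genome", "cds", "proteins", "gff3", "obo", "protein_map",
        "associations", "ppi", "truth_tracts", "truth_homoaa",
        "conservation", "planted_term"))
  }
  sim
}

#' @export
print.tnr_sim <- function(x, ...) {
  cat(sprintf("Synthetic dataset: genome %s nt, %d genes, %d planted DNA tracts, %d planted homo-AA runs\n",
              format(x$config$genome_length, big.mark = ","),
              x$config$n_genes,
              if (is.null(x$truth_tracts)) 0L else nrow(x$truth_tracts),
              if (is.null(x$truth_homoaa)) 0L else nrow(x$truth_homoaa)))
  invisible(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @param width line wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}
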