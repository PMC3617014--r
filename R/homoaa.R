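AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Homo-amino-acid tract parameters
#'
#' @param min_run_length minimum homo-AA run length in residues (default 7).
#' @param min_same_codon_run minimum consecutive identical-codon run for a
#'   tract to be called TNR-encoded (default 7).
#' @return An object of class \code{"homoaa_params"}.
#' @export
homoaa_params <- function(min_run_length = 7L, min_same_codon_run = 7L) {
  min_run_length <- as.integer(min_run_length)
  min_same_codon_run <- as.integer(min_same_codon_run)
  if (min_run_length < 2L || min_same_codon_run < 2L)
    stop("both thresholds must be >= 2")
  if (min_same_codon_run > min_run_length)
    stop("min_same_codon_run must be <= min_run_length")
  structure(list(min_run_length = min_run_length,
                 min_same_codon_run = min_same_codon_run),
            class = "homoaa_params")
}

#' Find homo-amino-acid runs in a protein sequence
#'
#' All maximal runs of a single standard amino acid with length at least
#' \code{min_run_length}. Non-standard letters (X, B, Z, U, *) break runs
#' and never form runs themselves.
#'
#' @param protein_seq protein sequence string.
#' @param params a \code{\link{homoaa_params}} object.
#' @return Data frame with \code{residue} and 0-based half-open
#'   \code{start}, \code{end}, plus \code{length} in residues.
#' @examples
#' find_homoaa_runs("MQQQQQQQA")  # one poly-Q run, residues 1..8
#' @export
find_homoaa_runs <- function(protein_seq, params = homoaa_params()) {
  empty <- data.frame(residue = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(protein_seq)) return(empty)
  ch <- strsplit(toupper(protein_seq), "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  ok <- r$lengths >= params$min_run_length & r$values %in% AA_STANDARD
  if (!any(ok)) return(empty)
  data.frame(residue = r$values[ok], start = starts[ok], end = ends[ok],
             length = r$lengths[ok], stringsAsFactors = FALSE)
}

#' Classify a homo-AA tract as TNR- or variant-encoded
#'
#' Computes the longest run of identical codons within the tract's codon
#' slice; the tract is TNR-encoded when that run reaches
#' \code{min_same_codon_run} consecutive residues, variant-encoded
#' otherwise. Each codon must translate to the tract residue.
#'
#' @param codons character vector of codons (one per tract residue).
#' @param residue the tract's amino acid (1-letter).
#' @param params a \code{\link{homoaa_params}} object.
#' @return List with \code{encoding_class} (\code{"tnr"} or
#'   \code{"variant"}) and \code{max_same_codon_run}.
#' @examples
#' classify_encoding(rep("CAG", 8), "Q")                    # tnr, run 8
#' classify_encoding(rep(c("CAA", "CAG"), 4), "Q")          # variant, run 1
#' @export
classify_encoding <- function(codons, residue, params = homoaa_params()) {
  codons <- toupper(codons)
  aa <- unname(GENCODE[codons])
  if (anyNA(aa) || any(aa != toupper(residue)))
    stop("codon does not translate to tract residue ", residue)
  mx <- max(rle(codons)$lengths)
  list(encoding_class = if (mx >= params$min_same_codon_run) "tnr"
       else "variant",
       max_same_codon_run = as.integer(mx))
}

#' Reverse-map a homo-AA tract to genomic coordinates
#'
#' Converts a residue span to its CDS nucleotide span (3 nt per residue) and
#' then, via the gene model's spliced CDS segments in transcription order, to
#' genomic intervals on forward coordinates, split at intron boundaries.
#' For minus-strand genes, transcription order runs from the highest to the
#' lowest genomic coordinate; the returned intervals are normalised to
#' forward-strand coordinates with the strand recorded.
#'
#' @param tract_start,tract_end 0-based half-open residue span.
#' @param gene_model one element of a \code{"gene_models"} object's
#'   \code{models} list.
#' @return Data frame \code{seqid}, 0-based half-open \code{start},
#'   \code{end}, \code{strand}; interval lengths sum to
#'   \code{3 * (tract_end - tract_start)}.
#' @export
map_tract_to_genome <- function(tract_start, tract_end, gene_model) {
  cds <- gene_model$cds
  widths <- GenomicRanges::width(cds)
  cds_len <- sum(widths)
  nt0 <- 3L * tract_start
  nt1 <- 3L * tract_end
  if (nt1 > cds_len) stop("tract extends past the CDS")
  starts1 <- GenomicRanges::start(cds)  # 1-based, ascending genomic order
  ends1 <- GenomicRanges::end(cds)
  if (gene_model$strand == "+") {
    ord <- order(starts1)
  } else {
    ord <- order(-starts1)
  }
  out <- list()
  off <- 0L
  for (k in ord) {
    w <- widths[k]
    lo <- max(nt0 - off, 0L)
    hi <- min(nt1 - off, w)
    if (hi > lo) {
      if (gene_model$strand == "+") {
        gs <- starts1[k] - 1L + lo
        ge <- starts1[k] - 1L + hi
      } else {
        # transcription runs from ends1[k] downwards
        gs <- ends1[k] - hi
        ge <- ends1[k] - lo
      }
      out[[length(out) + 1L]] <- data.frame(
        seqid = gene_model$seqid, start = gs, end = ge,
        strand = gene_model$strand, stringsAsFactors = FALSE)
    }
    off <- off + w
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

format_loci <- function(loci) {
  paste(sprintf("%s:%d-%d:%s", loci$seqid, loci$start, loci$end,
                loci$strand), collapse = ";")
}

#' Parse a semicolon-joined genomic-loci string
#'
#' Inverse of the \code{genomic_loci} serialisation used in tract tables
#' (\code{chrom:start-end:strand}, 0-based half-open, joined by \code{;}).
#'
#' @param x character vector of loci strings.
#' @return List of data frames (\code{seqid}, \code{start}, \code{end},
#'   \code{strand}).
#' @export
parse_loci <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(seqid = character(0), start = integer(0),
                        end = integer(0), strand = character(0)))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    pos <- lapply(parts, function(p) {
      se <- as.integer(strsplit(p[2L], "-", fixed = TRUE)[[1L]])
      data.frame(seqid = p[1L], start = se[1L], end = se[2L],
                 strand = p[3L], stringsAsFactors = FALSE)
    })
    do.call(rbind, pos)
  })
}

#' Scan a proteome for homo-AA tracts and classify their encoding
#'
#' Detects homo-AA runs in every protein, slices the matching codons out of
#' the protein's CDS, classifies each run as TNR- or variant-encoded, and
#' (when gene models are supplied) reverse-maps each run to genomic loci.
#' Proteins whose recorded CDS does not translate to the protein sequence
#' are dropped with a warning.
#'
#' @param proteins named character vector (or \code{AAStringSet}) of protein
#'   sequences, named by protein id.
#' @param cds_seqs named character vector (or \code{DNAStringSet}) of CDS
#'   sequences, named by gene id (stop codon optional).
#' @param map data frame with columns \code{protein_id}, \code{gene_id}.
#' @param params a \code{\link{homoaa_params}} object.
#' @param gene_models optional \code{"gene_models"} object for genomic loci.
#' @return Homo-AA tract table: \code{protein_id}, \code{gene_id},
#'   \code{residue}, 0-based half-open residue \code{start}/\code{end},
#'   \code{length}, \code{encoding_class}, \code{max_same_codon_run},
#'   \code{genomic_loci} (semicolon-joined, or \code{NA}).
#' @export
scan_proteome <- function(proteins, cds_seqs, map,
                          params = homoaa_params(), gene_models = NULL) {
  if (inherits(proteins, "AAStringSet")) proteins <- as.character(proteins)
  cds_seqs <- as_seq_char(cds_seqs)
  rows <- list()
  for (i in seq_len(nrow(map))) {
    pid <- map$protein_id[i]
    gid <- map$gene_id[i]
    prot <- proteins[[pid]]
    cds <- cds_seqs[[gid]]
    if (is.null(prot) || is.null(cds) || is.na(prot) || is.na(cds)) next
    ncod <- nchar(cds) %/% 3L
    codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    aa <- unname(GENCODE[codons])
    if (length(aa) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      codons <- codons[-length(codons)]
    }
    if (length(aa) != nchar(prot) ||
        paste(aa, collapse = "") != toupper(prot)) {
      warning("CDS does not translate to protein; dropped: ", pid)
      next
    }
    runs <- find_homoaa_runs(prot, params)
    if (nrow(runs) == 0L) next
    gm <- if (!is.null(gene_models)) gene_models$models[[gid]] else NULL
    for (j in seq_len(nrow(runs))) {
      cl <- classify_encoding(codons[(runs$start[j] + 1L):runs$end[j]],
                              runs$residue[j], params)
      loci <- NA_character_
      if (!is.null(gm))
        loci <- format_loci(map_tract_to_genome(runs$start[j], runs$end[j],
                                                gm))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, gene_id = gid, residue = runs$residue[j],
        start = runs$start[j], end = runs$end[j], length = runs$length[j],
        encoding_class = cl$encoding_class,
        max_same_codon_run = cl$max_same_codon_run,
        genomic_loci = loci, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), gene_id = character(0),
                      residue = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      encoding_class = character(0),
                      max_same_codon_run = integer(0),
                      genomic_loci = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build TNR- and variant-encoded protein sets
#'
#' A protein joins the TNR-encoded set if at least one of its homo-AA tracts
#' is TNR-encoded, and the variant-encoded set if at least one is
#' variant-encoded; a protein carrying both tract classes is a member of
#' both sets (so per-class counts may sum to more than the union).
#'
#' @param tracts homo-AA tract table from \code{\link{scan_proteome}}.
#' @return List with character vectors \code{tnr}, \code{variant},
#'   \code{all} (the union).
#' @export
build_protein_sets <- function(tracts) {
  tnr <- unique(tracts$protein_id[tracts$encoding_class == "tnr"])
  variant <- unique(tracts$protein_id[tracts$encoding_class == "variant"])
  list(tnr = tnr, variant = variant, all = union(tnr, variant))
}
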