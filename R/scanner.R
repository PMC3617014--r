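#' Scanner scoring parameters
#'
#' Parameters of the tandem-repeat alignment score used to detect and report
#' tracts: a fixed reward per matching nucleotide and fixed penalties per
#' mismatching or inserted/deleted nucleotide, with a minimum reporting score.
#' The defaults (match 2, mismatch 7, indel 7, minimum score 40, maximum
#' period 3) imply that the shortest reportable pure tract is
#' \code{min_score / match} = 20 nt.
#'
#' @param match score gained per matching nucleotide (default 2).
#' @param mismatch score lost per mismatching nucleotide (default 7).
#' @param indel score lost per inserted or deleted nucleotide (default 7).
#' @param min_score minimum alignment score for a tract to be reported
#'   (default 40).
#' @param max_period largest repeat unit length considered, 1-3 (default 3).
#' @return An object of class \code{"scan_params"}.
#' @export
scan_params <- function(match = 2L, mismatch = 7L, indel = 7L,
                        min_score = 40L, max_period = 3L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  indel <- as.integer(indel); min_score <- as.integer(min_score)
  max_period <- as.integer(max_period)
  if (any(c(match, mismatch, indel) <= 0L)) stop("all weights must be > 0")
  if (!max_period %in% 1:3) stop("max_period must be 1, 2 or 3")
  structure(list(match = match, mismatch = mismatch, indel = indel,
                 min_score = min_score, max_period = max_period),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(
    "Tandem repeat scan parameters: match +%d, mismatch -%d, indel -%d, min score %d, max period %d\n",
    x$match, x$mismatch, x$indel, x$min_score, x$max_period))
  cat(sprintf("  (shortest reportable pure tract: %d nt)\n",
              ceiling(x$min_score / x$match)))
  invisible(x)
}

#' Score a sequence against indefinite repetition of a unit
#'
#' Computes the maximum global wraparound-alignment score of \code{seq}
#' against indefinite repetition of \code{unit}: \code{+match} per matching
#' nucleotide, \code{-mismatch} per substitution, \code{-indel} per inserted
#' or deleted nucleotide. \code{N} never matches. The empty sequence scores 0.
#'
#' @param seq DNA string over ACGTN.
#' @param unit repeat unit, 1 to \code{max_period} nt over ACGT.
#' @param params a \code{\link{scan_params}} object.
#' @return A list with \code{score}, \code{matches}, \code{mismatches},
#'   \code{indels}.
#' @examples
#' score_tract(strrep("CAG", 7), "CAG")  # score 42, 21 matches
#' @export
score_tract <- function(seq, unit, params = scan_params()) {
  u <- encode_dna(unit)
  if (length(u) < 1L || length(u) > params$max_period)
    stop("unit length must be in [1, max_period]")
  if (any(u > 3L)) stop("unit must contain only A, C, G, T")
  s <- encode_dna(seq)
  r <- C_score_tract(s, u, params$match, params$mismatch, params$indel)
  list(score = r[1], matches = r[2], mismatches = r[3], indels = r[4])
}

#' Canonical repeat unit
#'
#' Lexicographically smallest rotation of a repeat unit, used to aggregate
#' the phase-equivalent forms of a unit (e.g. CAG, AGC and GCA all report
#' canonical unit AGC). Vectorised.
#'
#' @param unit character vector of units over ACGT.
#' @return character vector of canonical units.
#' @examples
#' canonical_unit(c("CAG", "AAT", "GTC"))  # "AGC" "AAT" "CGT"
#' @export
canonical_unit <- function(unit) {
  vapply(unit, function(u) {
    u <- toupper(u)
    ch <- strsplit(u, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% DNA_BASES4)) stop("unit must contain only A, C, G, T: ", u)
    k <- length(ch)
    rots <- vapply(seq_len(k), function(i)
      paste(ch[c(i:k, seq_len(i - 1L))[seq_len(k)]], collapse = ""), "")
    min(rots)
  }, "", USE.NAMES = FALSE)
}

# greedy maximal non-overlapping selection among scored candidates;
# order: score desc, length desc, start asc, canonical unit asc
select_tracts <- function(cand, seqchar) {
  if (nrow(cand) == 0L) return(cand)
  len <- cand$end - cand$start
  units <- substr(rep(seqchar, nrow(cand)), cand$start + 1L, cand$start + cand$period)
  cu <- canonical_unit(units)
  ord <- order(-cand$score, -len, cand$start, cu)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Seed windows: regions that could contain a reportable tract. Any tract with
# score >= min_score must contain >= 4 consecutive positions matching at lag p
# (a stretch where every match run is <= 3 loses >= 1 per 4 nt and cannot
# sustain a qualifying score), so windows are built from lag-p match runs of
# length >= 3 (one below the bound, for safety), merged within 50 nt and
# padded by 32 nt.
seed_windows <- function(codes, max_period, gap = 50L, pad = 32L) {
  n <- length(codes)
  hit <- logical(max(n - 1L, 0L))
  for (p in seq_len(max_period)) {
    if (n <= p) next
    m <- codes[seq_len(n - p)] == codes[(p + 1L):n] & codes[seq_len(n - p)] <= 3L
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= 3L
    for (i in which(ok)) hit[starts[i]:min(ends[i], n - 1L)] <- TRUE
  }
  if (!any(hit)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ws <- starts[r$values]; we <- ends[r$values] + 1L  # cover the lagged partner
  # merge windows separated by <= gap, then pad
  ms <- ws[1]; me <- we[1]; out_s <- integer(0); out_e <- integer(0)
  if (length(ws) > 1L) for (i in 2:length(ws)) {
    if (ws[i] - me <= gap) me <- max(me, we[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- ws[i]; me <- we[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = pmax(out_s - pad, 1L), end = pmin(out_e + pad, n))
}

scan_one <- function(seqchar, seqname, params) {
  codes <- encode_dna(seqchar)
  n <- length(codes)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      unit = character(0), canonical_unit = character(0),
                      copies = numeric(0), score = integer(0),
                      matches = integer(0), mismatches = integer(0),
                      indels = integer(0), purity = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < ceiling(params$min_score / params$match)) return(empty)
  win <- seed_windows(codes, params$max_period)
  if (nrow(win) == 0L) return(empty)
  cands <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    sub <- codes[win$start[w]:win$end[w]]
    m <- C_enumerate_candidates(sub, params$max_period, params$match,
                                params$mismatch, params$indel, params$min_score)
    if (nrow(m) == 0L) next
    d <- as.data.frame(m)
    d$start <- d$start + win$start[w] - 1L  # back to 0-based genome coords
    d$end <- d$end + win$start[w] - 1L
    cands[[w]] <- d
  }
  cand <- do.call(rbind, cands)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- unique(cand)
  sel <- select_tracts(cand, seqchar)
  if (nrow(sel) == 0L) return(empty)
  unit <- substr(rep(seqchar, nrow(sel)), sel$start + 1L, sel$start + sel$period)
  aligned <- sel$matches + sel$mismatches + sel$indels
  data.frame(sequence_id = seqname, start = sel$start, end = sel$end,
             period = sel$period, unit = unit,
             canonical_unit = canonical_unit(unit),
             copies = (sel$end - sel$start) / sel$period,
             score = sel$score, matches = sel$matches,
             mismatches = sel$mismatches, indels = sel$indels,
             purity = sel$matches / aligned, stringsAsFactors = FALSE)
}

#' Scan DNA for short-period tandem repeat tracts
#'
#' Exact maximal-scoring search for tandem repeat tracts of period up to
#' \code{max_period} under the wraparound alignment score of
#' \code{\link{score_tract}}. All maximal non-overlapping tracts reaching
#' \code{min_score} are reported; among overlapping candidates the
#' highest-scoring wins, with ties broken by longer tract, then smaller
#' start, then lexicographically smaller canonical unit. Tracts never start
#' or end on N; internal N bases score as mismatches.
#'
#' @param seqs named character vector of DNA sequences, or a
#'   \code{DNAStringSet}, or a single string.
#' @param params a \code{\link{scan_params}} object.
#' @return A tract table (data frame): \code{sequence_id}, 0-based half-open
#'   \code{start}/\code{end}, \code{period}, observed leading \code{unit},
#'   \code{canonical_unit}, real-valued \code{copies} (length / period),
#'   \code{score}, \code{matches}, \code{mismatches}, \code{indels},
#'   \code{purity} (matches / aligned columns), sorted by sequence then start.
#' @examples
#' scan_tnr(c(chr1 = paste0(strrep("TTACGGAT", 6), strrep("CAG", 20),
#'                          strrep("ATCCGTTG", 6))))
#' @export
scan_tnr <- function(seqs, params = scan_params()) {
  seqs <- as_seq_char(seqs)
  out <- lapply(seq_along(seqs), function(i)
    scan_one(seqs[[i]], names(seqs)[i], params))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter scanned tracts to genuine period-3 repeats
#'
#' Retains tracts assigned period 3 whose unit is not a disguised lower-period
#' repeat: the unit must contain at least two distinct bases, and the tract's
#' best period-1 or period-2 score (maximised over all 1-mer and 2-mer units)
#' must not exceed its period-3 score. Mono- and di-nucleotide repeats are
#' thereby removed, mirroring the removal of period-1 and period-2 tracts
#' before downstream analysis.
#'
#' @param tracts tract table from \code{\link{scan_tnr}}.
#' @param seqs the sequences that were scanned (needed to re-score tract
#'   substrings at lower periods).
#' @param params a \code{\link{scan_params}} object.
#' @return The filtered tract table.
#' @export
filter_period3 <- function(tracts, seqs, params = scan_params()) {
  if (nrow(tracts) == 0L) return(tracts)
  seqs <- as_seq_char(seqs)
  keep <- logical(nrow(tracts))
  units12 <- c(DNA_BASES4,
               apply(expand.grid(DNA_BASES4, DNA_BASES4), 1L,
                     paste, collapse = ""))
  for (i in seq_len(nrow(tracts))) {
    if (tracts$period[i] != 3L) next
    ch <- strsplit(tracts$unit[i], "", fixed = TRUE)[[1L]]
    if (length(unique(ch)) < 2L) next
    sub <- substr(seqs[[tracts$sequence_id[i]]], tracts$start[i] + 1L,
                  tracts$end[i])
    best12 <- max(vapply(units12, function(u)
      score_tract(sub, u, params)$score, 0))
    keep[i] <- best12 <= tracts$score[i]
  }
  out <- tracts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a tract table as TSV
#'
#' Plain TSV serialisation of the tract tables produced by
#' \code{\link{scan_tnr}} (and annotated by \code{\link{localize_tracts}}).
#' Coordinates are 0-based half-open.
#'
#' @param tracts tract table.
#' @param path file path.
#' @return \code{write_tracts_tsv} returns \code{path} invisibly;
#'   \code{read_tracts_tsv} returns the tract table.
#' @export
write_tracts_tsv <- function(tracts, path) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracts_tsv
#' @export
read_tracts_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write tracts as BED6
#'
#' BED6 export of a tract table: name is the canonical unit, score is the
#' alignment score capped at 1000, strand is \code{+} (scanning is
#' plus-strand only).
#'
#' @param tracts tract table.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_tracts_bed <- function(tracts, path) {
  bed <- data.frame(tracts$sequence_id, tracts$start, tracts$end,
                    tracts$canonical_unit, pmin(tracts$score, 1000L), "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
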