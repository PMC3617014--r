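REGION_CLASSES <- c("exonic", "utr5", "utr3", "intron", "upstream",
                    "intergenic")

#' Load gene models from GFF3, one splice variant per gene
#'
#' Parses a GFF3 annotation (gene/mRNA/exon/CDS/five_prime_UTR/
#' three_prime_UTR hierarchy) and keeps exactly one splice variant per gene:
#' either the variant with the longest total CDS (default) or the first
#' listed in the file. Genes without CDS, and variants whose CDS length is
#' not divisible by 3, are dropped with a warning. A fixed-width upstream
#' window abutting the transcription start (strand-aware) is attached to
#' every retained model.
#'
#' @param gff3 path to a GFF3 file.
#' @param variant_rule \code{"longest_cds"} (default) or
#'   \code{"first_listed"}.
#' @param upstream upstream window width in nt (default 1000).
#' @param exclude_seqs optional character vector of sequence ids to drop
#'   (e.g. organellar or unplaced sequences).
#' @return An object of class \code{"gene_models"}: a list of per-gene
#'   models (each with \code{gene_id}, \code{protein_id}, \code{seqid},
#'   \code{strand} and \code{GRanges} components \code{exons}, \code{cds},
#'   \code{utr5}, \code{utr3}, \code{introns}, \code{upstream}) plus
#'   precomputed per-class ranges used for position classification.
#' @export
load_annotation <- function(gff3, variant_rule = c("longest_cds",
                                                   "first_listed"),
                            upstream = 1000L, exclude_seqs = NULL) {
  variant_rule <- match.arg(variant_rule)
  gr <- rtracklayer::import(gff3, format = "gff3")
  if (!is.null(exclude_seqs))
    gr <- gr[!as.character(GenomicRanges::seqnames(gr)) %in% exclude_seqs]
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, "")

  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  mrna_parent <- parents[type == "mRNA"]
  if (length(mrnas) > 0L && anyNA(mrna_parent))
    stop("malformed GFF3: mRNA without Parent")
  feat_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  feats <- gr[type %in% feat_types]
  feat_parent <- parents[type %in% feat_types]
  if (length(feats) > 0L && anyNA(feat_parent))
    stop("malformed GFF3: feature without Parent")
  mrna_ids <- as.character(mrnas$ID)
  bad_parent <- !feat_parent %in% mrna_ids
  if (any(bad_parent))
    stop("malformed GFF3: feature Parent not an mRNA: ",
         paste(unique(feat_parent[bad_parent])[1:3], collapse = ", "))

  models <- list()
  for (gi in seq_along(genes)) {
    gid <- as.character(genes$ID[gi])
    vids <- mrna_ids[mrna_parent == gid]
    if (length(vids) == 0L) {
      warning("gene without mRNA dropped: ", gid)
      next
    }
    cds_len <- vapply(vids, function(v)
      sum(GenomicRanges::width(feats[feat_parent == v &
                                       as.character(feats$type) == "CDS"])),
      0)
    if (all(cds_len == 0)) {
      warning("gene without CDS dropped: ", gid)
      next
    }
    vid <- switch(variant_rule,
                  longest_cds = vids[which.max(cds_len)],
                  first_listed = vids[cds_len > 0][1L])
    if (cds_len[vid] %% 3 != 0) {
      warning("CDS length not divisible by 3; model rejected: ", gid)
      next
    }
    m <- mrnas[mrna_ids == vid]
    strand <- as.character(GenomicRanges::strand(m))
    seqid <- as.character(GenomicRanges::seqnames(m))
    pick <- function(t) {
      f <- feats[feat_parent == vid & as.character(feats$type) == t]
      GenomicRanges::sort(GenomicRanges::granges(f))
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    span <- range(c(GenomicRanges::start(m), GenomicRanges::end(m)))
    introns <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(seqid, IRanges::IRanges(span[1], span[2]),
                             strand = "*"),
      GenomicRanges::GRanges(GenomicRanges::seqnames(exons),
                             IRanges::IRanges(GenomicRanges::start(exons),
                                              GenomicRanges::end(exons))))
    tss <- if (strand == "+") span[1] else span[2]
    up <- if (strand == "+")
      GenomicRanges::GRanges(seqid,
                             IRanges::IRanges(max(1L, tss - upstream), tss - 1L))
    else
      GenomicRanges::GRanges(seqid, IRanges::IRanges(tss + 1L, tss + upstream))
    pid <- if (!is.null(m$protein_id) && !is.na(m$protein_id[1L]))
      as.character(m$protein_id[1L]) else NA_character_
    models[[gid]] <- list(gene_id = gid, protein_id = pid, seqid = seqid,
                          strand = strand, exons = exons, cds = cds,
                          utr5 = pick("five_prime_UTR"),
                          utr3 = pick("three_prime_UTR"),
                          introns = introns, upstream = up,
                          mrna_id = vid, span = span)
  }
  build_gene_models(models, upstream)
}

# assemble the "gene_models" container, with per-class GRanges (gene-tagged)
build_gene_models <- function(models, upstream_width) {
  class_gr <- list()
  comp <- c(exonic = "cds", utr5 = "utr5", utr3 = "utr3",
            intron = "introns", upstream = "upstream")
  for (cl in names(comp)) {
    parts <- lapply(models, function(m) {
      g <- m[[comp[[cl]]]]
      if (length(g) == 0L) return(NULL)
      g <- GenomicRanges::granges(g)
      GenomicRanges::strand(g) <- "*"
      g$gene_id <- m$gene_id
      g$protein_id <- m$protein_id
      g
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    class_gr[[cl]] <- if (length(parts)) do.call(c, unname(parts))
    else GenomicRanges::GRanges()
  }
  # mutually exclusive position classification: each class region minus all
  # higher-precedence regions (exonic > utr5 > utr3 > intron > upstream)
  exclusive <- list()
  higher <- GenomicRanges::GRanges()
  for (cl in names(comp)) {
    r <- GenomicRanges::reduce(class_gr[[cl]])
    exclusive[[cl]] <- GenomicRanges::setdiff(r, higher)
    higher <- GenomicRanges::reduce(c(higher, r))
  }
  structure(list(models = models, class_granges = class_gr,
                 exclusive_granges = exclusive,
                 upstream_width = upstream_width),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("%d gene models (one splice variant each), upstream window %d nt\n",
              length(x$models), x$upstream_width))
  invisible(x)
}

#' Classify a genomic position into a region class
#'
#' Assigns exactly one of \code{exonic} (coding), \code{utr5}, \code{utr3},
#' \code{intron}, \code{upstream}, \code{intergenic} to a position, using
#' that precedence when features of several genes overlap.
#'
#' @param models a \code{"gene_models"} object.
#' @param sequence_id sequence (chromosome) name.
#' @param position 1-based genomic position (vectorised).
#' @return Character vector of region classes.
#' @export
classify_position <- function(models, sequence_id, position) {
  known <- unique(vapply(models$models, `[[`, "", "seqid"))
  if (length(known) && !sequence_id %in% known)
    stop("unknown sequence_id: ", sequence_id)
  q <- GenomicRanges::GRanges(sequence_id,
                              IRanges::IRanges(position, position))
  out <- rep("intergenic", length(q))
  for (cl in c("upstream", "intron", "utr3", "utr5", "exonic")) {
    hit <- IRanges::overlapsAny(q, models$exclusive_granges[[cl]])
    out[hit] <- cl
  }
  out
}

#' Localize repeat tracts to gene regions
#'
#' Assigns each tract the region class with maximal nucleotide overlap
#' (ties broken by the precedence exonic > utr5 > utr3 > intron > upstream >
#' intergenic) and links tracts in genic classes (exonic, UTRs, intron) to
#' the overlapping gene and protein.
#'
#' @param tracts tract table with 0-based half-open \code{start}/\code{end}.
#' @param models a \code{"gene_models"} object.
#' @return The tract table with \code{region_class}, \code{gene_id},
#'   \code{protein_id} columns appended.
#' @export
localize_tracts <- function(tracts, models) {
  n <- nrow(tracts)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  prot <- rep(NA_character_, n)
  if (n > 0L) {
    tr <- GenomicRanges::GRanges(tracts$sequence_id,
                                 IRanges::IRanges(tracts$start + 1L,
                                                  tracts$end))
    ovw <- matrix(0L, n, 5L,
                  dimnames = list(NULL, c("exonic", "utr5", "utr3", "intron",
                                          "upstream")))
    best_gene <- matrix(NA_character_, n, 5L, dimnames = dimnames(ovw))
    best_prot <- matrix(NA_character_, n, 5L, dimnames = dimnames(ovw))
    for (cl in colnames(ovw)) {
      # nucleotide overlap against the mutually exclusive class regions
      # (so a CDS base never also counts as another gene's upstream base)
      x <- models$exclusive_granges[[cl]]
      if (length(x) > 0L) {
        hx <- GenomicRanges::findOverlaps(tr, x)
        if (length(hx) > 0L) {
          wx <- GenomicRanges::width(IRanges::pintersect(
            tr[S4Vectors::queryHits(hx)], x[S4Vectors::subjectHits(hx)]))
          agg <- tapply(wx, S4Vectors::queryHits(hx), sum)
          ovw[as.integer(names(agg)), cl] <- as.integer(agg)
        }
      }
      # per tract, the gene contributing the most feature overlap per class
      g <- models$class_granges[[cl]]
      if (length(g) == 0L) next
      h <- GenomicRanges::findOverlaps(tr, g)
      if (length(h) == 0L) next
      w <- GenomicRanges::width(IRanges::pintersect(
        tr[S4Vectors::queryHits(h)], g[S4Vectors::subjectHits(h)]))
      d <- data.frame(q = S4Vectors::queryHits(h), w = w,
                      gid = g$gene_id[S4Vectors::subjectHits(h)],
                      pid = g$protein_id[S4Vectors::subjectHits(h)],
                      stringsAsFactors = FALSE)
      d <- d[order(d$q, -d$w), ]
      d <- d[!duplicated(d$q), ]
      best_gene[d$q, cl] <- d$gid
      best_prot[d$q, cl] <- d$pid
    }
    has <- rowSums(ovw) > 0L
    if (any(has)) {
      prec <- c("exonic", "utr5", "utr3", "intron", "upstream")
      for (i in which(has)) {
        wmax <- max(ovw[i, ])
        cl <- prec[ovw[i, prec] == wmax][1L]  # precedence breaks ties
        region[i] <- cl
        if (cl != "upstream") {
          gene[i] <- best_gene[i, cl]
          prot[i] <- best_prot[i, cl]
        }
      }
    }
  }
  tracts$region_class <- region
  tracts$gene_id <- gene
  tracts$protein_id <- prot
  tracts
}
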