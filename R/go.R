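#' Parse an OBO 1.2 ontology (is_a / part_of subset)
#'
#' Reads \code{[Term]} stanzas with \code{id}, \code{name}, \code{is_a},
#' \code{relationship: part_of} and \code{is_obsolete} fields. Other
#' relationship types (e.g. \code{has_part}, \code{regulates}) are ignored,
#' and obsolete terms are excluded, so the retained graph is the
#' is_a/part_of closure graph. A cycle over the retained edges is an error.
#'
#' @param path path to an OBO file (or a character vector of its lines via
#'   \code{text}).
#' @param text optional character vector of OBO lines, used instead of
#'   \code{path}.
#' @return An object of class \code{"ontology"}: \code{terms} (data frame
#'   \code{id}, \code{name}), \code{edges} (data frame \code{child},
#'   \code{parent}, \code{type}), \code{roots}.
#' @export
parse_obo <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- trimws(lines)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- which(grepl("^\\[.*\\]$", lines))
  ids <- character(0); names_ <- character(0); obso <- logical(0)
  edges <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    blk <- lines[(s + 1L):end]
    get1 <- function(key) {
      v <- blk[startsWith(blk, paste0(key, ":"))]
      if (length(v)) trimws(sub(paste0("^", key, ":"), "", v)) else character(0)
    }
    id <- get1("id")[1L]
    if (is.na(id) || !length(id)) next
    nm <- get1("name")
    ob <- any(grepl("^true", get1("is_obsolete")))
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) nm[1L] else id)
    obso <- c(obso, ob)
    if (ob) next
    for (p in get1("is_a")) {
      pid <- trimws(strsplit(p, "!", fixed = TRUE)[[1L]][1L])
      edges[[length(edges) + 1L]] <- c(id, pid, "is_a")
    }
    for (p in get1("relationship")) {
      parts <- strsplit(trimws(strsplit(p, "!", fixed = TRUE)[[1L]][1L]),
                        "[[:space:]]+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of")
        edges[[length(edges) + 1L]] <- c(id, parts[2L], "part_of")
    }
  }
  keep <- !obso
  terms <- data.frame(id = ids[keep], name = names_[keep],
                      stringsAsFactors = FALSE)
  ed <- if (length(edges))
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  else data.frame(V1 = character(0), V2 = character(0), V3 = character(0))
  names(ed) <- c("child", "parent", "type")
  ed <- ed[ed$child %in% terms$id & ed$parent %in% terms$id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                     vertices = terms$id)
  if (!igraph::is_dag(g)) stop("cycle over retained is_a/part_of edges")
  roots <- terms$id[igraph::degree(g, mode = "out") == 0L]
  structure(list(terms = terms, edges = ed, roots = roots, graph = g),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, %d is_a/part_of edges, %d root(s)\n",
              nrow(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Ancestors of a term (reflexive transitive closure)
#'
#' All terms reachable from \code{term} over is_a/part_of edges, including
#' the term itself.
#'
#' @param ontology an \code{"ontology"} object.
#' @param term term id.
#' @return Character vector of term ids.
#' @export
go_ancestors <- function(ontology, term) {
  if (!term %in% ontology$terms$id) stop("unknown term: ", term)
  sort(names(igraph::subcomponent(ontology$graph, term, mode = "out")))
}

#' Propagate gene-term associations up the ontology
#'
#' Each gene's annotation set is the union of the reflexive transitive
#' closures (over is_a/part_of) of its directly associated terms. Unknown
#' terms are skipped with a warning.
#'
#' @param ontology an \code{"ontology"} object.
#' @param associations data frame with columns \code{gene_id},
#'   \code{term_id}.
#' @return Named list: gene id -> character vector of term ids.
#' @export
propagate_annotations <- function(ontology, associations) {
  if (nrow(associations) == 0L) return(structure(list(), names = character(0)))
  unknown <- setdiff(unique(associations$term_id), ontology$terms$id)
  if (length(unknown)) {
    warning("skipping associations to unknown terms: ",
            paste(utils::head(unknown, 3L), collapse = ", "))
    associations <- associations[!associations$term_id %in% unknown, ,
                                 drop = FALSE]
  }
  anc <- lapply(unique(associations$term_id), go_ancestors,
                ontology = ontology)
  names(anc) <- unique(associations$term_id)
  sp <- split(associations$term_id, associations$gene_id)
  lapply(sp, function(ts) sort(unique(unlist(anc[ts], use.names = FALSE))))
}

#' GO term over-representation by Fisher's exact test
#'
#' For every term annotated to at least one background gene, tests whether
#' the study set is enriched for the term with a one-sided (greater)
#' Fisher exact test on the 2x2 table (study with/without term, non-study
#' background with/without term). The E-value is the Bonferroni-scaled
#' p-value, p times the number of terms tested, not capped at 1 by default.
#' Genes without annotations stay in the margins as "without term".
#'
#' @param study character vector of study gene/protein ids (must be a
#'   subset of \code{background}).
#' @param background character vector of background ids.
#' @param annotations propagated annotations from
#'   \code{\link{propagate_annotations}}.
#' @param ontology an \code{"ontology"} object (for term names).
#' @param alternative \code{"greater"} (default, over-representation) or
#'   \code{"two.sided"}.
#' @param cap_evalue cap E-values at 1 (default \code{FALSE}).
#' @return Data frame sorted by E-value: \code{term_id}, \code{term_name},
#'   \code{study_with}, \code{study_without}, \code{bg_with},
#'   \code{bg_without}, \code{p_value}, \code{e_value}.
#' @export
fisher_overrepresentation <- function(study, background, annotations,
                                      ontology,
                                      alternative = c("greater",
                                                      "two.sided"),
                                      cap_evalue = FALSE) {
  alternative <- match.arg(alternative)
  study <- unique(study); background <- unique(background)
  if (length(study) == 0L || length(background) == 0L)
    stop("study and background must be non-empty")
  if (!all(study %in% background))
    stop("study must be a subset of background")
  ann <- annotations[names(annotations) %in% background]
  terms <- sort(unique(unlist(ann, use.names = FALSE)))
  if (length(terms) == 0L) stop("no term annotates any background gene")
  m <- length(terms)
  nS <- length(study); nB <- length(background)
  in_study <- names(ann) %in% study
  rows <- lapply(terms, function(t) {
    has <- vapply(ann, function(v) t %in% v, TRUE)
    bg_with <- sum(has)
    st_with <- sum(has & in_study)
    if (alternative == "greater") {
      p <- stats::phyper(st_with - 1L, bg_with, nB - bg_with, nS,
                         lower.tail = FALSE)
    } else {
      p <- stats::fisher.test(matrix(c(st_with, nS - st_with,
                                       bg_with - st_with,
                                       (nB - nS) - (bg_with - st_with)),
                                     2L, 2L))$p.value
    }
    data.frame(term_id = t,
               term_name = ontology$terms$name[match(t, ontology$terms$id)],
               study_with = st_with, study_without = nS - st_with,
               bg_with = bg_with, bg_without = nB - bg_with,
               p_value = p, e_value = if (cap_evalue) min(1, p * m) else p * m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$e_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
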