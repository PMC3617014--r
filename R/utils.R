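#' @useDynLib tnrscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# cached copy: avoids repeated lazy-load fetches in codon-level loops
GENCODE <- Biostrings::GENETIC_CODE

# character string -> integer codes A=0,C=1,G=2,T=3, anything else 4 (N)
encode_dna <- function(x) {
  stopifnot(length(x) == 1L)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  m <- match(v, DNA_BASES4)
  m[is.na(m)] <- 5L
  as.integer(m - 1L)
}

decode_dna <- function(codes) {
  paste(c(DNA_BASES4, "N")[codes + 1L], collapse = "")
}

# Accept a named character vector, a single string, or a Biostrings
# DNAStringSet / DNAString; return a named character vector of sequences.
as_seq_char <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (inherits(x, "DNAString")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be character or DNAStringSet")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  toupper(x)
}

# deterministic per-stage seed fan-out from one master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
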