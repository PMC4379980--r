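#' @importFrom methods as is
#' @importFrom stats sd runif rbinom setNames
#' @importFrom utils read.delim write.table head tail
NULL

.datatable.aware <- TRUE

# Internal coordinates are 0-based half-open throughout; conversion to the
# 1-based inclusive convention happens only at the GFF3 boundary.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
PURINES <- c("A", "G")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param x character scalar (A/C/G/T/N)
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring of a contig in 0-based half-open coordinates
seq_slice <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(va != vb)
}

#' Derive a per-stage RNG seed from the run seed
#'
#' Each stochastic stage draws from an independently derived stream so the
#' stages are order-independent and a run is reproducible end to end.
#'
#' @param seed integer run seed
#' @param stage character stage name
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

assert_dna <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-DNA characters: %s", what,
                 paste(bad, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

# shared alignment scoring: nucleotide +2/-1, with IUPAC ambiguity support
.pkg_cache <- new.env(parent = emptyenv())

nuc_submat <- function() {
  if (is.null(.pkg_cache$nuc)) {
    .pkg_cache$nuc <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE)
  }
  .pkg_cache$nuc
}

# stringent matrix for boundary refinement: random sequence pairs score
# negative even when base composition is skewed, so Smith-Waterman cannot
# drift past the true homology ends
nuc_submat_strict <- function() {
  if (is.null(.pkg_cache$nuc_strict)) {
    .pkg_cache$nuc_strict <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
  }
  .pkg_cache$nuc_strict
}

blosum62 <- function() {
  if (is.null(.pkg_cache$b62)) {
    e <- new.env()
    utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$b62 <- get("BLOSUM62", envir = e)
  }
  .pkg_cache$b62
}

# standard error of the mean; 0 for n == 1 (degenerate-group convention)
se_mean <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}
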