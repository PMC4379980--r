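#' Extract translated reverse-transcriptase domains from classified elements
#'
#' Uses the RT domain hits recorded by [classify_elements()] (recomputing
#' them if absent), translates each hit region in its frame and keeps
#' sequences of at least `min_rt_aa` amino acids (default 80); shorter hits
#' and elements without an RT hit are dropped.
#'
#' @param elements classified element table (with the `domain_hits`
#'   attribute set by [classify_elements()])
#' @param seqs sequence list from [element_sequences()]
#' @param library domain library (used only if hits must be recomputed)
#' @param config [run_config()]
#' @return named character vector of RT protein sequences
#' @export
extract_rt <- function(elements, seqs, library = load_domain_library(),
                       config = run_config()) {
  hit_list <- attr(elements, "domain_hits")
  out <- character(0)
  for (i in seq_len(nrow(elements))) {
    id <- elements$element_id[i]
    hits <- if (!is.null(hit_list)) hit_list[[id]]
            else find_domains(seqs$internal[[id]], library, config)
    if (is.null(hits) || nrow(hits) == 0L) next
    rt <- hits[hits$label == "RT", , drop = FALSE]
    if (nrow(rt) == 0L) next
    rt <- rt[which.max(rt$score), ]
    nt <- seq_slice(seqs$internal[[id]], rt$start, rt$end)
    if (startsWith(rt$frame, "-")) nt <- revcomp(nt)
    nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
    prot <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(nt), if.fuzzy.codon = "solve")))
    if (nchar(prot) >= config$min_rt_aa) out[id] <- prot
  }
  out
}

#' Pairwise p-distances between protein sequences
#'
#' Each pair is globally aligned (BLOSUM62, gap open 11 / extend 1) and the
#' distance is 1 - identity over the gap-free aligned columns.
#'
#' @param seqs named character vector of >= 2 protein sequences
#' @return symmetric numeric matrix with zero diagonal
#' @export
protein_distances <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  mat <- blosum62()
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[[i]], seqs[[j]], type = "global",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ok <- a != "-" & b != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) sum(a[ok] != b[ok]) / sum(ok) else 1
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch-length
#' estimates (a known NJ artefact on noisy matrices) are clamped to zero
#' and flagged in the `clamped` attribute.
#'
#' @param d symmetric distance matrix with labels
#' @return `phylo` tree (unrooted)
#' @export
nj_tree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- sum(neg)
  }
  tr
}

# star alignment of sequences onto reference columns: every sequence is
# globally aligned to the reference; the residue (or '-') facing each
# reference position is recorded. An approximation of a multiple alignment
# sufficient for column resampling.
star_alignment <- function(seqs) {
  mat <- blosum62()
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  ncol <- nchar(ref)
  M <- matrix("-", length(seqs), ncol, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    if (i == ref_i) { M[i, ] <- strsplit(ref, "")[[1]]; next }
    aln <- Biostrings::pairwiseAlignment(
      ref, seqs[[i]], type = "global",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    M[i, ] <- b[a != "-"]
  }
  M
}

p_dist_from_columns <- function(M) {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) sum(M[i, ok] != M[j, ok]) / sum(ok) else 1
  }
  d
}

#' Bootstrap support for the NJ tree of a protein set
#'
#' Columns of a star alignment (all sequences projected onto the positions
#' of the longest one) are resampled with replacement; each replicate
#' matrix of p-distances is rebuilt into an NJ tree and the proportion of
#' replicates containing each bipartition of the original tree is reported.
#'
#' @param seqs named character vector of >= 4 protein sequences
#' @param replicates number of bootstrap replicates (default 100)
#' @param seed RNG seed for the resampling stream
#' @return list: `tree` (the original NJ tree), `support` (numeric vector
#'   in `[0,1]`, one value per internal node in [ape::prop.clades()] order)
#' @export
bootstrap_support <- function(seqs, replicates = 100L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  M <- star_alignment(seqs)
  tree <- nj_tree(p_dist_from_columns(M))
  set.seed(derive_seed(seed, "bootstrap"))
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    reps[[r]] <- nj_tree(p_dist_from_columns(M[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  list(tree = tree, support = counts / replicates)
}

#' Single-linkage family clusters from a distance matrix
#'
#' Family delimitation: elements whose RT domains are connected by chains
#' of pairwise distances at most `cutoff` form one family.
#'
#' @param d distance matrix
#' @param cutoff single-linkage height (default 0.25)
#' @return data.frame: `element_id`, `family` (`FAM1`, `FAM2`, ... in order
#'   of first appearance)
#' @export
family_clusters <- function(d, cutoff = 0.25) {
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = cutoff)
  fam <- paste0("FAM", match(cl, unique(cl)))
  data.frame(element_id = names(cl), family = fam, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a tree to a newick file
#' @param tree `phylo`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick file
#' @param path newick file
#' @return `phylo`
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
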