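#' Translate a DNA sequence in all six reading frames
#'
#' @param dna DNA string (length >= 3)
#' @return named character vector of proteins for frames `+1`, `+2`, `+3`,
#'   `-1`, `-2`, `-3`; stop codons rendered as `*`, ambiguous codons as `X`
#' @export
six_frame_translate <- function(dna) {
  assert_dna(dna, "translation input")
  if (nchar(dna) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  fwd <- dna
  rev <- revcomp(dna)
  one <- function(s, off) {
    s <- substr(s, off, nchar(s))
    s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
    if (nchar(s) < 3L) return("")
    suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "solve")))
  }
  stats::setNames(
    c(one(fwd, 1L), one(fwd, 2L), one(fwd, 3L),
      one(rev, 1L), one(rev, 2L), one(rev, 3L)),
    c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Load the bundled retroelement protein-domain library
#'
#' Synthetic stand-in reference domains (GAG, PR, INT, RT, RH, CHD; one
#' Copia-like and one Gypsy-like variant each), shipped as FASTA and
#' user-replaceable. Record ids must follow `<Superfamily>_<LABEL>`.
#'
#' @param path optional FASTA path overriding the bundled file
#' @return data.frame with `id`, `superfamily`, `label`, `seq`
#' @export
load_domain_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domain_proteins_synthetic.fasta",
                        package = "ltrpipe", mustWork = TRUE)
  }
  seqs <- read_fasta(path, type = "protein")
  ids <- names(seqs)
  parts <- strsplit(ids, "_", fixed = TRUE)
  data.frame(
    id = ids,
    superfamily = vapply(parts, `[`, "", 1L),
    label = vapply(parts, function(p) p[length(p)], ""),
    seq = unname(seqs),
    stringsAsFactors = FALSE)
}

#' Find protein domains in an element's internal region
#'
#' Translated Smith-Waterman search: each of the six frame translations is
#' locally aligned against every library domain (BLOSUM62, gap open 11 /
#' extend 1); the best hit per domain label per frame with score at least
#' `domain_score_min` is kept, and overlapping same-label hits are merged
#' keeping the best score. Hit intervals are reported in nucleotide
#' coordinates on the internal region (0-based half-open).
#'
#' @param internal_seq internal (inter-LTR) region sequence
#' @param library domain library from [load_domain_library()]
#' @param config [run_config()]
#' @return data.frame: `label`, `frame`, `start`, `end`, `score`,
#'   `ref_superfamily`; sorted by `start`
#' @export
find_domains <- function(internal_seq, library = load_domain_library(),
                         config = run_config()) {
  if (nrow(library) == 0L) stop("empty domain library", call. = FALSE)
  if (length(unique(library$label)) < 1L) stop("empty domain library", call. = FALSE)
  prots <- six_frame_translate(internal_seq)
  L <- nchar(internal_seq)
  mat <- blosum62()
  hits <- list()
  for (fr in names(prots)) {
    p <- prots[[fr]]
    if (nchar(p) < 10L) next
    # '*' (stop) is not rewarded by BLOSUM62 in local search; leave it in --
    # the alignment simply avoids crossing it. One vectorized call aligns
    # the whole library against this frame.
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(library$seq), p, type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    pass <- which(sc >= config$domain_score_min)
    if (length(pass) == 0L) next
    aa_s <- Biostrings::start(Biostrings::subject(aln))[pass]
    aa_e <- Biostrings::end(Biostrings::subject(aln))[pass]
    off <- as.integer(substr(fr, 2L, 2L)) - 1L
    if (startsWith(fr, "+")) {
      nt_s <- off + 3L * (aa_s - 1L)
      nt_e <- off + 3L * aa_e
    } else {
      nt_s <- L - (off + 3L * aa_e)
      nt_e <- L - (off + 3L * (aa_s - 1L))
    }
    hits[[length(hits) + 1L]] <- data.frame(
      label = library$label[pass], frame = fr, start = nt_s, end = nt_e,
      score = sc[pass], ref_superfamily = library$superfamily[pass],
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) {
    return(data.frame(label = character(), frame = character(),
                      start = integer(), end = integer(), score = numeric(),
                      ref_superfamily = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # best hit per label per frame
  out <- out[order(out$label, out$frame, -out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("label", "frame")]), , drop = FALSE]
  # merge overlapping same-label hits, best score wins
  out <- out[order(out$label, -out$score), , drop = FALSE]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    same <- which(keep & out$label == out$label[i])
    ov <- length(same) > 0 &&
      any(out$start[i] < out$end[same] & out$end[i] > out$start[same])
    if (!ov) keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an element's superfamily from its domain order
#'
#' Copia and Gypsy differ in the position of the integrase: upstream of the
#' reverse transcriptase in Copia (GAG-PR-INT-RT-RH), downstream of the
#' RNaseH in Gypsy (GAG-PR-RT-RH-INT). A chromodomain hit downstream of the
#' integrase marks the chromodomain-bearing Gypsy subgroup. Elements with
#' neither an RT nor an INT hit are `Unknown`. Hits are ordered along the
#' element's transcriptional direction, inferred from the score-weighted
#' majority of hit frames, so the call is strand-invariant. When only one of
#' INT/RT is present the order rule cannot apply and the call falls back to
#' the library superfamily of the best-scoring hit.
#'
#' @param hits data.frame from [find_domains()]
#' @return list: `superfamily` (`"Copia"`, `"Gypsy"`, `"Unknown"`),
#'   `chromodomain` (logical), `strand` (`"+"`, `"-"`, or `NA`),
#'   `domain_order` (character, dash-separated), `evidence` (the hits,
#'   ordered)
#' @export
classify_superfamily <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(superfamily = "Unknown", chromodomain = FALSE,
                strand = NA_character_, domain_order = "",
                evidence = hits))
  }
  minus_w <- sum(hits$score[startsWith(hits$frame, "-")])
  plus_w <- sum(hits$score[startsWith(hits$frame, "+")])
  strand <- if (minus_w > plus_w) "-" else "+"
  ord <- if (strand == "+") order(hits$start) else order(-hits$start)
  hits <- hits[ord, , drop = FALSE]
  labels <- hits$label
  domain_order <- paste(labels, collapse = "-")

  has_rt <- "RT" %in% labels
  has_int <- "INT" %in% labels
  if (!has_rt && !has_int) {
    return(list(superfamily = "Unknown", chromodomain = FALSE, strand = strand,
                domain_order = domain_order, evidence = hits))
  }
  super <- NULL
  if (has_rt && has_int) {
    int_pos <- which(labels == "INT")
    rt_pos <- which(labels == "RT")[1L]
    rh_pos <- if ("RH" %in% labels) which(labels == "RH")[1L] else rt_pos
    if (any(int_pos < rt_pos) && any(int_pos > rt_pos)) {
      warning("contradictory integrase placement; classifying as Unknown",
              call. = FALSE)
      return(list(superfamily = "Unknown", chromodomain = FALSE,
                  strand = strand, domain_order = domain_order,
                  evidence = hits))
    }
    super <- if (all(int_pos < rt_pos)) "Copia"
             else if (all(int_pos > rh_pos)) "Gypsy"
             else "Unknown"  # INT between RT and RH: no canonical order
  } else {
    key <- hits[hits$label %in% c("RT", "INT"), , drop = FALSE]
    super <- key$ref_superfamily[which.max(key$score)]
  }
  chd <- FALSE
  if (super == "Gypsy" && "CHD" %in% labels && has_int) {
    chd <- any(which(labels == "CHD") > which(labels == "INT")[1L])
  }
  list(superfamily = super, chromodomain = chd, strand = strand,
       domain_order = domain_order, evidence = hits)
}

#' Classify all elements and reclassify unknowns by nucleotide similarity
#'
#' Runs the translated domain search and order-based superfamily call on
#' each element's internal region, then attempts to rescue `Unknown`
#' elements by local nucleotide alignment against the classified ones: an
#' unknown inherits the superfamily of its best hit when the alignment
#' covers at least `reclass_min_len` nt at identity `reclass_min_identity`
#' or better.
#'
#' @param elements element table from [scan_contigs()]
#' @param seqs sequence list from [element_sequences()]
#' @param library domain library
#' @param config [run_config()]
#' @return the element table with added columns `superfamily`,
#'   `chromodomain`, `domain_order`, `n_domains`, `reclassified`, and
#'   `strand` updated from domain frames
#' @export
classify_elements <- function(elements, seqs, library = load_domain_library(),
                              config = run_config()) {
  n <- nrow(elements)
  elements$superfamily <- rep("Unknown", n)
  elements$chromodomain <- rep(FALSE, n)
  elements$domain_order <- rep("", n)
  elements$n_domains <- rep(0L, n)
  elements$reclassified <- rep(FALSE, n)
  hit_list <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- find_domains(seqs$internal[[elements$element_id[i]]], library, config)
    call <- classify_superfamily(hits)
    hit_list[[i]] <- call$evidence
    elements$superfamily[i] <- call$superfamily
    elements$chromodomain[i] <- call$chromodomain
    elements$domain_order[i] <- call$domain_order
    elements$n_domains[i] <- nrow(hits)
    if (!is.na(call$strand)) elements$strand[i] <- call$strand
  }
  # second pass: nucleotide-similarity rescue of unknowns
  unk <- which(elements$superfamily == "Unknown")
  cls <- which(elements$superfamily != "Unknown")
  if (length(unk) > 0 && length(cls) > 0) {
    for (i in unk) {
      qi <- seqs$element[[elements$element_id[i]]]
      best_sf <- NA_character_; best_sc <- -Inf
      for (j in cls) {
        aln <- Biostrings::pairwiseAlignment(
          qi, seqs$element[[elements$element_id[j]]], type = "local",
          substitutionMatrix = nuc_submat(), gapOpening = 10,
          gapExtension = 0.5)
        alen <- Biostrings::nchar(aln)
        ident <- Biostrings::pid(aln, type = "PID1") / 100
        if (alen >= config$reclass_min_len &&
            ident >= config$reclass_min_identity &&
            Biostrings::score(aln) > best_sc) {
          best_sc <- Biostrings::score(aln)
          best_sf <- elements$superfamily[j]
        }
      }
      if (!is.na(best_sf)) {
        elements$superfamily[i] <- best_sf
        elements$reclassified[i] <- TRUE
      }
    }
  }
  attr(elements, "domain_hits") <- stats::setNames(hit_list, elements$element_id)
  elements
}
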