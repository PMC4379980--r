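#' De novo detection of LTR pair candidates in a contig
#'
#' Finds pairs of long direct repeats compatible with the two LTRs of a
#' full-length retroelement. Exact k-mer seed matches between distinct
#' regions of the contig are grouped by diagonal (constant offset) into
#' collinear chains; each chain is evaluated as a candidate 5'/3' LTR pair
#' by global alignment and retained when it satisfies the configured length
#' and identity bounds. Overlapping candidates are reduced to the
#' highest-identity one per locus. Direct repeats are orientation-symmetric,
#' so a single forward scan covers elements inserted on either strand; the
#' transcriptional strand is assigned later from protein-domain frames.
#'
#' @param contig_seq contig sequence (character scalar, A/C/G/T/N)
#' @param contig_id contig name used in reported coordinates
#' @param config [run_config()] list; the detector keys are used
#' @return data.frame with one row per candidate: `contig`, 0-based
#'   half-open `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `ltr_identity`, `strand`
#' @export
find_ltr_pairs <- function(contig_seq, contig_id = "contig", config = run_config()) {
  n <- nchar(contig_seq)
  empty <- data.frame(contig = character(), ltr5_start = integer(),
                      ltr5_end = integer(), ltr3_start = integer(),
                      ltr3_end = integer(), ltr_identity = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n < config$min_contig_len) {
    warning(sprintf("contig %s (%d nt) below min_contig_len (%d nt); skipped",
                    contig_id, n, config$min_contig_len), call. = FALSE)
    return(empty)
  }
  k <- config$seed_kmer_len
  pos0 <- 0:(n - k)
  kmers <- substring(contig_seq, pos0 + 1L, pos0 + k)
  keep <- !grepl("N", kmers, fixed = TRUE)
  dt <- data.table::data.table(kmer = kmers[keep], i = pos0[keep])
  dt <- dt[, if (.N >= 2L && .N <= 50L) list(i = list(i)) else NULL, by = "kmer"]
  if (nrow(dt) == 0L) return(empty)

  # separation between LTR starts: element span = sep + ltr_len
  min_sep <- max(config$min_ltr_len, config$min_elem_len - config$max_ltr_len)
  max_sep <- config$max_elem_len - config$min_ltr_len
  pair_list <- lapply(dt$i, function(p) {
    p <- sort(p)
    cmb <- utils::combn(p, 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    ok <- d >= min_sep & d <= max_sep
    if (!any(ok)) return(NULL)
    data.table::data.table(i = cmb[1L, ok], d = d[ok])
  })
  seeds <- data.table::rbindlist(pair_list)
  if (is.null(seeds) || nrow(seeds) == 0L) return(empty)
  data.table::setorderv(seeds, c("d", "i"))

  # cluster seeds sharing a diagonal (small jitter allowed) into chains
  diag_tol <- 15L
  gap_tol <- 300L
  d <- seeds$d; i <- seeds$i
  new_cluster <- c(TRUE, diff(d) > diag_tol | abs(diff(i)) > gap_tol)
  cl <- cumsum(new_cluster)
  cand <- seeds[, list(
    i_min = min(i), i_max = max(i), d_med = as.integer(stats::median(d)),
    n_seeds = .N), by = list(cl = cl)]
  cand <- cand[cand$n_seeds >= 3L, ]
  if (nrow(cand) == 0L) return(empty)

  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s5 <- cand$i_min[r]; e5 <- cand$i_max[r] + k
    d0 <- cand$d_med[r]
    s3 <- s5 + d0; e3 <- e5 + d0
    len <- e5 - s5
    if (len < config$min_ltr_len || len > config$max_ltr_len) next
    span <- e3 - s5
    if (span < config$min_elem_len || span > config$max_elem_len) next
    if (e5 > s3 || e3 > n) next
    ident <- ltr_pair_identity(seq_slice(contig_seq, s5, e5),
                               seq_slice(contig_seq, s3, e3))
    if (ident < config$min_ltr_similarity) next
    rows[[r]] <- data.frame(contig = contig_id, ltr5_start = s5, ltr5_end = e5,
                            ltr3_start = s3, ltr3_end = e3,
                            ltr_identity = ident, strand = "+",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) return(empty)

  # reduce overlapping element spans to the highest-identity candidate
  out <- out[order(-out$ltr_identity), , drop = FALSE]
  kept <- logical(nrow(out))
  for (r in seq_len(nrow(out))) {
    overlaps <- FALSE
    if (any(kept)) {
      ks <- which(kept)
      overlaps <- any(out$ltr5_start[r] < out$ltr3_end[ks] &
                      out$ltr3_end[r] > out$ltr5_start[ks])
    }
    if (!overlaps) kept[r] <- TRUE
  }
  out <- out[kept, , drop = FALSE]
  out <- out[order(out$ltr5_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# global-alignment identity between two putative LTR copies
ltr_pair_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = nuc_submat(),
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Refine candidate LTR boundaries by local realignment and TG/CA snapping
#'
#' The two LTR neighbourhoods (candidate intervals padded on both sides) are
#' realigned with the Smith-Waterman algorithm; the local alignment proposes
#' corrected LTR extents. Termini are then snapped to the nearest TG
#' dinucleotide (LTR starts) and CA dinucleotide (LTR ends) within
#' `boundary_snap_window`, using one common offset per terminus pair so the
#' two LTRs stay length-compatible. When no snap target exists the original
#' coordinates are kept and `has_tg_ca` is `FALSE`; refinement never
#' discards a candidate, and it is idempotent.
#'
#' @param candidate one-row data.frame from [find_ltr_pairs()]
#' @param contig_seq the contig sequence
#' @param config [run_config()]
#' @return the candidate with (possibly) adjusted coordinates and a
#'   `has_tg_ca` logical column
#' @export
refine_boundaries <- function(candidate, contig_seq, config = run_config()) {
  stopifnot(nrow(candidate) == 1L)
  n <- nchar(contig_seq)
  w <- config$boundary_snap_window
  pad <- 4L * w

  p5s <- max(0L, candidate$ltr5_start - pad)
  p5e <- min(candidate$ltr3_start, candidate$ltr5_end + pad)
  p3s <- max(candidate$ltr5_end, candidate$ltr3_start - pad)
  p3e <- min(n, candidate$ltr3_end + pad)
  aln <- Biostrings::pairwiseAlignment(
    seq_slice(contig_seq, p5s, p5e), seq_slice(contig_seq, p3s, p3e),
    type = "local", substitutionMatrix = nuc_submat_strict(),
    gapOpening = 10, gapExtension = 0.5)
  prop5s <- p5s + Biostrings::start(Biostrings::pattern(aln)) - 1L
  prop5e <- p5s + Biostrings::end(Biostrings::pattern(aln))
  prop3s <- p3s + Biostrings::start(Biostrings::subject(aln)) - 1L
  prop3e <- p3s + Biostrings::end(Biostrings::subject(aln))

  # nearest common offset putting `motif` at both positions
  snap <- function(pos_a, pos_b, motif) {
    offs <- order(abs(seq(-w, w)), seq(-w, w))  # 0, -1, 1, -2, 2, ...
    for (o in seq(-w, w)[offs]) {
      a <- pos_a + o; b <- pos_b + o
      if (a < 0 || b + 2L > n) next
      if (substr(contig_seq, a + 1L, a + 2L) == motif &&
          substr(contig_seq, b + 1L, b + 2L) == motif) return(o)
    }
    NA_integer_
  }
  # the realigned extents are the primary anchors (they recover terminal
  # seed erosion on diverged LTR pairs); the raw seed extents are the
  # fallback when the realignment finds no snap target
  snap_pair <- function(a, b, motif) {
    o <- snap(a, b, motif)
    if (!is.na(o)) list(a = a + o, b = b + o) else NULL
  }
  st <- snap_pair(prop5s, prop3s, "TG")
  if (is.null(st)) st <- snap_pair(candidate$ltr5_start, candidate$ltr3_start, "TG")
  en <- snap_pair(prop5e - 2L, prop3e - 2L, "CA")
  if (is.null(en)) en <- snap_pair(candidate$ltr5_end - 2L, candidate$ltr3_end - 2L, "CA")

  out <- candidate
  if (!is.null(st) && !is.null(en)) {
    out$ltr5_start <- st$a
    out$ltr3_start <- st$b
    out$ltr5_end <- en$a + 2L
    out$ltr3_end <- en$b + 2L
    out$has_tg_ca <- TRUE
  } else {
    # no TG/CA pair in reach: keep the realigned homology extents (for an
    # undiverged pair these equal the seed extents, i.e. no change)
    out$ltr5_start <- prop5s; out$ltr5_end <- prop5e
    out$ltr3_start <- prop3s; out$ltr3_end <- prop3e
    out$has_tg_ca <- FALSE
  }
  if (out$ltr5_end > out$ltr3_start) { # realignment overshoot on tiny spacers
    out$ltr5_end <- candidate$ltr5_end; out$ltr3_start <- candidate$ltr3_start
  }
  out$ltr_identity <- ltr_pair_identity(
    seq_slice(contig_seq, out$ltr5_start, out$ltr5_end),
    seq_slice(contig_seq, out$ltr3_start, out$ltr3_end))
  out
}

# When the termini could not be snapped to TG/CA, try to re-anchor the
# element span on a target-site duplication: small joint offsets of the
# element start/end that expose a shared 4-6-mer flank. Longest TSD wins,
# then the smallest total offset.
tsd_rescue <- function(contig_seq, start0, end0, max_shift = 6L) {
  n <- nchar(contig_seq)
  best <- NULL
  for (L in 6:4) {
    for (o5 in -max_shift:max_shift) for (o3 in -max_shift:max_shift) {
      s <- start0 + o5; e <- end0 + o3
      if (s < L || e + L > n) next
      up <- seq_slice(contig_seq, s - L, s)
      down <- seq_slice(contig_seq, e, e + L)
      if (up != down) next
      cost <- abs(o5) + abs(o3)
      if (is.null(best) || L > best$L || (L == best$L && cost < best$cost)) {
        best <- list(o5 = o5, o3 = o3, L = L, tsd = up, cost = cost)
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' Detect a target-site duplication flanking an element
#'
#' Integration duplicates 4-6 nt of host sequence on both sides of the
#' element. Returns the longest exact match between the immediate upstream
#' suffix and downstream prefix of the element span; ties at equal length are
#' impossible by construction (the match abuts the element on both sides).
#'
#' @param contig_seq contig sequence
#' @param start0,end0 element span, 0-based half-open
#' @return the TSD string, or `NA_character_` if none (or if the element sits
#'   at a contig edge, with a warning)
#' @export
detect_tsd <- function(contig_seq, start0, end0) {
  n <- nchar(contig_seq)
  if (start0 < 6L || end0 + 6L > n) {
    warning("element too close to contig edge for TSD detection", call. = FALSE)
    return(NA_character_)
  }
  up <- seq_slice(contig_seq, start0 - 6L, start0)
  down <- seq_slice(contig_seq, end0, end0 + 6L)
  for (L in 6:4) {
    cand <- substr(up, 7L - L, 6L)
    if (cand == substr(down, 1L, L)) return(cand)
  }
  NA_character_
}

#' Detect a primer-binding site downstream of the 5' LTR
#'
#' Scans a window immediately 3' of the 5' LTR for a 15-18 nt stretch whose
#' sequence matches the reverse complement of the 3'-terminal portion of a
#' tRNA oligo (i.e. is complementary to the tRNA 3' end) with at most
#' `pbs_max_mismatches` mismatches. The best hit (fewest mismatches, then
#' smallest offset, then longest match) is returned.
#'
#' @param contig_seq contig sequence
#' @param ltr5_end0 0-based end of the 5' LTR
#' @param trna_oligos named character vector of tRNA 3'-end oligos (3'
#'   terminus at the right end of each string); see [load_trna_oligos()]
#' @param config [run_config()]
#' @return list with `start`, `end` (0-based half-open contig coordinates),
#'   `trna`, `mismatches`, or `NULL` when no qualifying hit exists
#' @export
detect_pbs <- function(contig_seq, ltr5_end0, trna_oligos, config = run_config()) {
  if (length(trna_oligos) == 0) stop("empty tRNA oligo library", call. = FALSE)
  n <- nchar(contig_seq)
  win_len <- min(config$pbs_window, n - ltr5_end0)
  if (win_len < 15L) return(NULL)
  window <- seq_slice(contig_seq, ltr5_end0, ltr5_end0 + win_len)
  best <- NULL
  for (ti in seq_along(trna_oligos)) {
    oligo <- trna_oligos[[ti]]
    for (L in 15:18) {
      if (nchar(oligo) < L) next
      target <- revcomp(substr(oligo, nchar(oligo) - L + 1L, nchar(oligo)))
      for (off in 0:(win_len - L)) {
        mm <- hamming(substr(window, off + 1L, off + L), target)
        if (mm > config$pbs_max_mismatches) next
        better <- is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches && off < best$off) ||
          (mm == best$mismatches && off == best$off && L > best$len)
        if (better) {
          best <- list(start = ltr5_end0 + off, end = ltr5_end0 + off + L,
                       trna = names(trna_oligos)[ti], mismatches = mm,
                       off = off, len = L)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best[c("start", "end", "trna", "mismatches")]
}

#' Detect a polypurine tract upstream of the 3' LTR
#'
#' Within a window directly upstream of the 3' LTR, returns the 20-25 nt
#' stretch with the highest purine (A/G) fraction, provided that fraction is
#' at least `ppt_min_purine`. Ties are broken towards the window closest to
#' the LTR, then towards the longer window.
#'
#' @param contig_seq contig sequence
#' @param ltr3_start0 0-based start of the 3' LTR
#' @param config [run_config()]
#' @return list with `start`, `end`, `purine_fraction`, or `NULL`
#' @export
detect_ppt <- function(contig_seq, ltr3_start0, config = run_config()) {
  win_s <- max(0L, ltr3_start0 - config$ppt_window)
  window <- seq_slice(contig_seq, win_s, ltr3_start0)
  wn <- nchar(window)
  if (wn < 20L) return(NULL)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  is_pur <- chars %in% PURINES
  cum <- c(0L, cumsum(is_pur))
  best <- NULL
  for (L in 20:25) {
    if (L > wn) break
    for (s in 0:(wn - L)) {
      frac <- (cum[s + L + 1L] - cum[s + 1L]) / L
      if (frac < config$ppt_min_purine) next
      better <- is.null(best) || frac > best$purine_fraction ||
        (frac == best$purine_fraction && s + L > best$rel_end) ||
        (frac == best$purine_fraction && s + L == best$rel_end && L > best$len)
      if (better) {
        best <- list(start = win_s + s, end = win_s + s + L,
                     purine_fraction = frac, rel_end = s + L, len = L)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best[c("start", "end", "purine_fraction")]
}

#' Scan contigs for full-length LTR retroelements
#'
#' Applies the contig length filter, detects LTR pair candidates, refines
#' their boundaries and scores the four structural features (TG...CA
#' termini, TSD, PBS, PPT) for each. Candidates missing more than
#' `missing_features_allowed` features (default 1) are dropped, reflecting
#' that genuine full-length elements occasionally lack one feature.
#'
#' @param contigs named character vector of contig sequences
#' @param config [run_config()]
#' @param trna_oligos tRNA 3'-end oligo set; defaults to the bundled library
#' @return data.frame of elements sorted by contig then start: coordinates
#'   (0-based half-open), `ltr_identity`, `has_tg_ca`, `tsd`, PBS/PPT
#'   intervals, `ppt_purine`, `n_missing`, `element_id`
#' @export
scan_contigs <- function(contigs, config = run_config(),
                         trna_oligos = load_trna_oligos()) {
  all_rows <- list()
  for (cid in names(contigs)) {
    cseq <- contigs[[cid]]
    if (nchar(cseq) < config$min_contig_len) next
    cands <- find_ltr_pairs(cseq, cid, config)
    if (nrow(cands) == 0L) next
    for (r in seq_len(nrow(cands))) {
      cand <- refine_boundaries(cands[r, , drop = FALSE], cseq, config)
      start0 <- cand$ltr5_start; end0 <- cand$ltr3_end
      tsd <- suppressWarnings(detect_tsd(cseq, start0, end0))
      if (!cand$has_tg_ca && is.na(tsd)) {
        # termini not snappable: re-anchor the span on a TSD if one is close
        resc <- tsd_rescue(cseq, start0, end0)
        if (!is.null(resc)) {
          cand$ltr5_start <- start0 + resc$o5
          cand$ltr3_end <- end0 + resc$o3
          start0 <- cand$ltr5_start; end0 <- cand$ltr3_end
          tsd <- resc$tsd
        }
      }
      pbs <- detect_pbs(cseq, cand$ltr5_end, trna_oligos, config)
      ppt <- detect_ppt(cseq, cand$ltr3_start, config)
      n_missing <- sum(!cand$has_tg_ca, is.na(tsd), is.null(pbs), is.null(ppt))
      if (n_missing > config$missing_features_allowed) next
      row <- cand
      row$start <- start0; row$end <- end0
      row$tsd <- tsd
      row$pbs_start <- if (is.null(pbs)) NA_integer_ else pbs$start
      row$pbs_end <- if (is.null(pbs)) NA_integer_ else pbs$end
      row$ppt_start <- if (is.null(ppt)) NA_integer_ else ppt$start
      row$ppt_end <- if (is.null(ppt)) NA_integer_ else ppt$end
      row$ppt_purine <- if (is.null(ppt)) NA_real_ else ppt$purine_fraction
      row$n_missing <- n_missing
      all_rows[[length(all_rows) + 1L]] <- row
    }
  }
  if (length(all_rows) == 0L) {
    warning("no full-length LTR retroelements detected", call. = FALSE)
    out <- data.frame(contig = character(), ltr5_start = integer(),
                      ltr5_end = integer(), ltr3_start = integer(),
                      ltr3_end = integer(), ltr_identity = numeric(),
                      strand = character(), has_tg_ca = logical(),
                      start = integer(), end = integer(), tsd = character(),
                      pbs_start = integer(), pbs_end = integer(),
                      ppt_start = integer(), ppt_end = integer(),
                      ppt_purine = numeric(), n_missing = integer(),
                      element_id = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, all_rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out$element_id <- sprintf("%s_RE%d", out$contig,
                            stats::ave(seq_len(nrow(out)), out$contig,
                                       FUN = seq_along))
  rownames(out) <- NULL
  # every reported candidate must satisfy its own invariants
  stopifnot(all(out$ltr5_end <= out$ltr3_start),
            all(out$ltr_identity >= config$min_ltr_similarity),
            all(out$end - out$start <= config$max_elem_len))
  out
}

#' Extract element, LTR and internal-region sequences for an element table
#'
#' @param elements element table from [scan_contigs()]
#' @param contigs named character vector of contig sequences
#' @return list with named character vectors `element`, `ltr5`, `ltr3`,
#'   `internal` (inter-LTR region), indexed by `element_id`
#' @export
element_sequences <- function(elements, contigs) {
  get <- function(s, e) {
    vapply(seq_len(nrow(elements)), function(i) {
      seq_slice(contigs[[elements$contig[i]]], s[i], e[i])
    }, "")
  }
  out <- list(
    element = get(elements$start, elements$end),
    ltr5 = get(elements$ltr5_start, elements$ltr5_end),
    ltr3 = get(elements$ltr3_start, elements$ltr3_end),
    internal = get(elements$ltr5_end, elements$ltr3_start))
  lapply(out, stats::setNames, elements$element_id)
}

#' Load the bundled tRNA 3'-end oligo library
#'
#' A small synthetic stand-in set of 18-mers (constructed, not drawn from a
#' curated tRNA database); replace with your own FASTA via `path` for real
#' analyses.
#'
#' @param path optional FASTA path overriding the bundled file
#' @return named character vector of oligos
#' @export
load_trna_oligos <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trna_3prime_oligos_synthetic.fasta",
                        package = "ltrpipe", mustWork = TRUE)
  }
  read_fasta(path, type = "DNA")
}
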