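#' Truncate reads to a constant length
#'
#' Bases beyond `len` are cut (prefix kept) so every read contributes the
#' same weight to the redundancy statistics; shorter reads pass unchanged.
#'
#' @param reads named character vector of read sequences
#' @param len maximum read length (default 75 nt)
#' @return named character vector
#' @export
truncate_reads <- function(reads, len = 75L) {
  if (length(reads) == 0L) return(reads)
  too_long <- nchar(reads) > len
  reads[too_long] <- substr(reads[too_long], 1L, len)
  reads
}

#' Map reads to a set of reference sequences
#'
#' k-mer seeded ungapped mapper. Seed matches between a read (either
#' orientation) and a reference define candidate diagonals; each candidate
#' is evaluated as an ungapped placement of the whole read on the reference.
#' A placement is accepted when the in-reference part of the read aligns at
#' identity at least `min_identity` and covers at least
#' `min_length_fraction` of the read. With `edge_clip = TRUE`, placements
#' that run over a reference edge are also accepted when at least half the
#' read aligns in-reference at the identity threshold (reference-edge soft
#' clipping); this is how partition mapping counts junction-spanning reads
#' by the partition holding the majority of their aligned bases. Each read
#' is assigned to at most one reference: the placement with the most
#' matching bases wins, and ties between references are resolved by a
#' seeded uniform draw (`tie_policy = "random"`) or by reference input
#' order (`"first"`).
#'
#' @param reads named character vector (pre-truncated)
#' @param references named character vector of reference sequences
#' @param config [run_config()]; uses `min_identity`,
#'   `min_length_fraction`, `map_kmer_len`
#' @param seed integer seed for the multiread stream
#' @param tie_policy `"random"` or `"first"`
#' @param edge_clip accept reference-edge alignments covering >= half the
#'   read (used by [ltr_ratio()])
#' @return data.frame: `read_id`, `ref`, `pos` (0-based start of the read
#'   placement on the reference, may be negative under `edge_clip`),
#'   `strand`, `matches`, `aligned_len`, `identity`
#' @export
map_reads <- function(reads, references, config = run_config(), seed = 1L,
                      tie_policy = c("random", "first"), edge_clip = FALSE) {
  tie_policy <- match.arg(tie_policy)
  k <- config$map_kmer_len
  empty <- data.frame(read_id = character(), ref = character(),
                      pos = integer(), strand = character(),
                      matches = integer(), aligned_len = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  usable <- nchar(references) >= k
  if (any(!usable)) {
    warning("reference(s) shorter than kmer_len skipped: ",
            paste(names(references)[!usable], collapse = ", "), call. = FALSE)
    references <- references[usable]
  }
  if (length(references) == 0L) return(empty)

  # reference k-mer index
  idx <- data.table::rbindlist(lapply(names(references), function(rn) {
    s <- references[[rn]]
    p <- 0:(nchar(s) - k)
    data.table::data.table(kmer = substring(s, p + 1L, p + k), ref = rn, rpos = p)
  }))

  # read k-mers, both orientations
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  mk_q <- function(seqs, strand) {
    lens <- nchar(seqs)
    ok <- which(lens >= k)
    if (length(ok) == 0L) return(NULL)
    # vectorize k-mer extraction across reads sharing a length
    parts <- lapply(split(ok, lens[ok]), function(ids) {
      L <- lens[ids[1L]]
      data.table::rbindlist(lapply(0:(L - k), function(p) {
        data.table::data.table(rid = ids, strand = strand,
                               kmer = substr(seqs[ids], p + 1L, p + k),
                               qpos = p)
      }))
    })
    data.table::rbindlist(parts)
  }
  q <- data.table::rbindlist(list(mk_q(unname(reads), "+"), mk_q(unname(rc), "-")))
  if (is.null(q) || nrow(q) == 0L) return(empty)
  data.table::setkey(idx, "kmer")
  hits <- idx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  hits[, `:=`(diag = hits$rpos - hits$qpos)]
  cand <- unique(hits[, c("rid", "strand", "ref", "diag")])

  rlen <- nchar(reads)
  reflen <- nchar(references)
  n_cand <- nrow(cand)
  m <- rlen[cand$rid]
  nr <- reflen[cand$ref]
  lo <- pmax(0L, cand$diag)
  hi <- pmin(nr, cand$diag + m)
  inref <- hi - lo
  # evaluate identities (loop over candidates; candidate sets are small)
  matches <- integer(n_cand)
  for (i in seq_len(n_cand)) {
    if (inref[i] < k) { matches[i] <- 0L; next }
    rseq <- if (cand$strand[i] == "+") reads[[cand$rid[i]]] else rc[[cand$rid[i]]]
    a <- substr(references[[cand$ref[i]]], lo[i] + 1L, hi[i])
    b <- substr(rseq, lo[i] - cand$diag[i] + 1L, hi[i] - cand$diag[i])
    matches[i] <- sum(strsplit(a, "", fixed = TRUE)[[1]] ==
                      strsplit(b, "", fixed = TRUE)[[1]])
  }
  identity <- ifelse(inref > 0, matches / inref, 0)
  full_cov <- inref >= config$min_length_fraction * m
  at_edge <- cand$diag < 0L | cand$diag + m > nr
  clip_ok <- edge_clip & at_edge & inref >= 0.5 * m
  accepted <- identity >= config$min_identity & (full_cov | clip_ok)
  if (!any(accepted)) return(empty)

  acc <- cand[accepted, ]
  acc$matches <- matches[accepted]
  acc$aligned_len <- inref[accepted]
  acc$identity <- identity[accepted]

  # one assignment per read: most matching bases; seeded draw among ties
  set.seed(derive_seed(seed, "map_reads"))
  acc_split <- split(seq_len(nrow(acc)), acc$rid)
  rids <- sort(as.integer(names(acc_split)))
  picks <- integer(length(rids))
  for (j in seq_along(rids)) {
    rows <- acc_split[[as.character(rids[j])]]
    best <- rows[acc$matches[rows] == max(acc$matches[rows])]
    # a read may tie with itself on several diagonals/strands of one ref;
    # collapse to one candidate per reference (first by position)
    first_per_ref <- best[!duplicated(acc$ref[best])]
    picks[j] <- if (length(first_per_ref) == 1L) first_per_ref
      else if (tie_policy == "first") {
        first_per_ref[order(match(acc$ref[first_per_ref], names(references)))][1L]
      } else {
        first_per_ref[sample.int(length(first_per_ref), 1L)]
      }
  }
  out <- data.frame(
    read_id = names(reads)[rids], ref = acc$ref[picks],
    pos = acc$diag[picks], strand = acc$strand[picks],
    matches = acc$matches[picks], aligned_len = acc$aligned_len[picks],
    identity = acc$identity[picks], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Redundancy as mapped reads per kb of reference
#'
#' @param assignments data.frame from [map_reads()]
#' @param references named character vector used for the mapping
#' @return data.frame: `ref`, `length_nt`, `mapped_reads`, `reads_per_kb`
#'   (one row per reference, zero counts included)
#' @export
reads_per_kb <- function(assignments, references) {
  counts <- table(factor(assignments$ref, levels = names(references)))
  data.frame(
    ref = names(references),
    length_nt = unname(nchar(references)),
    mapped_reads = as.integer(counts),
    reads_per_kb = as.numeric(counts) / (unname(nchar(references)) / 1000),
    stringsAsFactors = FALSE)
}

#' LTR vs inter-LTR coverage ratio for one element
#'
#' Maps the read set against two references -- the element's 5' LTR and its
#' inter-LTR (internal) region; the 3' LTR is excluded so that a family
#' consisting only of intact elements has an expected ratio of 2 (each
#' intact copy carries two LTR copies per internal region, and 3'-LTR reads
#' map onto the 5'-LTR reference). Solo LTRs left by unequal homologous
#' recombination add LTR coverage only, so with N intact copies and S solo
#' LTRs the expected ratio is (2N+S)/N; a ratio above
#' `solo_ratio_threshold` (default 2.5) flags a solo-LTR-rich family.
#' Junction-spanning reads are counted for the partition holding the
#' majority of their aligned bases (reference-edge soft clipping; exact
#' ties go to the LTR partition).
#'
#' @param ltr5_seq 5' LTR sequence
#' @param internal_seq inter-LTR region sequence
#' @param reads named character vector of (truncated) reads
#' @param config [run_config()]
#' @param seed seed for the mapping stream
#' @return list: `rpk_ltr`, `rpk_inter`, `ratio` (`Inf` when the internal
#'   partition receives no reads but the LTR does, `NaN` when neither
#'   does), `solo_flag` (`NA` when the ratio is undefined), `n_ltr`,
#'   `n_inter`
#' @export
ltr_ratio <- function(ltr5_seq, internal_seq, reads, config = run_config(),
                      seed = 1L) {
  refs <- c(LTR = ltr5_seq, INTERNAL = internal_seq)
  asn <- map_reads(reads, refs, config, seed = seed,
                   tie_policy = "first", edge_clip = TRUE)
  rpk <- reads_per_kb(asn, refs)
  rpk_ltr <- rpk$reads_per_kb[rpk$ref == "LTR"]
  rpk_int <- rpk$reads_per_kb[rpk$ref == "INTERNAL"]
  ratio <- if (rpk_int == 0 && rpk_ltr == 0) NaN else rpk_ltr / rpk_int
  solo <- if (is.nan(ratio)) NA else ratio > config$solo_ratio_threshold
  list(rpk_ltr = rpk_ltr, rpk_inter = rpk_int, ratio = ratio,
       solo_flag = solo,
       n_ltr = rpk$mapped_reads[rpk$ref == "LTR"],
       n_inter = rpk$mapped_reads[rpk$ref == "INTERNAL"])
}

#' Per-element redundancy and solo-LTR statistics for an element set
#'
#' Runs the whole-set redundancy mapping (all elements as one reference
#' set, multireads randomly assigned) and the per-element LTR/inter-LTR
#' partition mapping.
#'
#' @param elements classified element table
#' @param seqs sequence list from [element_sequences()]
#' @param reads named character vector of raw reads (truncated internally)
#' @param config [run_config()]
#' @param seed mapping seed
#' @return data.frame keyed by `element_id`: `mapped_reads`,
#'   `reads_per_kb`, `rpk_ltr`, `rpk_inter`, `ratio`, `solo_flag`
#' @export
element_redundancy <- function(elements, seqs, reads, config = run_config(),
                               seed = 1L) {
  reads <- truncate_reads(reads, config$read_truncate_len)
  asn <- map_reads(reads, seqs$element, config, seed = seed)
  rpk <- reads_per_kb(asn, seqs$element)
  out <- data.frame(element_id = elements$element_id, stringsAsFactors = FALSE)
  out$mapped_reads <- rpk$mapped_reads[match(out$element_id, rpk$ref)]
  out$reads_per_kb <- rpk$reads_per_kb[match(out$element_id, rpk$ref)]
  out$rpk_ltr <- NA_real_; out$rpk_inter <- NA_real_
  out$ratio <- NA_real_; out$solo_flag <- NA
  for (i in seq_len(nrow(out))) {
    id <- out$element_id[i]
    st <- ltr_ratio(seqs$ltr5[[id]], seqs$internal[[id]], reads, config,
                    seed = derive_seed(seed, id))
    out$rpk_ltr[i] <- st$rpk_ltr
    out$rpk_inter[i] <- st$rpk_inter
    out$ratio[i] <- st$ratio
    out$solo_flag[i] <- st$solo_flag
  }
  out
}
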