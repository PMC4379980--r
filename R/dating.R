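#' Align the two LTRs of an element and summarise their divergence
#'
#' Needleman-Wunsch global alignment (match +2, mismatch -1, gap open -10,
#' extend -0.5) followed by complete deletion of gapped columns: every
#' column containing an indel is removed before distances are computed, so
#' only substitutions contribute to the divergence estimate.
#'
#' @param five_ltr_seq,three_ltr_seq the two LTR sequences (>= 50 nt each)
#' @return list: `aligned_cols`, `indel_free_cols`, `mismatches`,
#'   `p_distance`
#' @export
align_ltr_pair <- function(five_ltr_seq, three_ltr_seq) {
  if (!nzchar(five_ltr_seq) || !nzchar(three_ltr_seq)) {
    stop("empty LTR sequence", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    five_ltr_seq, three_ltr_seq, type = "global",
    substitutionMatrix = nuc_submat(), gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  aligned_cols <- length(a)
  ok <- a != "-" & b != "-"
  mism <- sum(a[ok] != b[ok])
  L <- sum(ok)
  list(aligned_cols = aligned_cols, indel_free_cols = L, mismatches = mism,
       p_distance = if (L > 0) mism / L else NA_real_)
}

#' Jukes-Cantor corrected distance
#'
#' `K = -(3/4) * log(1 - (4/3) * p)`, the one-parameter-model correction of
#' an observed proportion of differing sites.
#'
#' @param p observed p-distance, `0 <= p < 0.75`
#' @return corrected distance K
#' @export
jc_distance <- function(p) {
  if (any(p < 0)) stop("negative p-distance", call. = FALSE)
  if (any(p >= 0.75)) {
    stop("p-distance at or beyond the Jukes-Cantor saturation limit (0.75)",
         call. = FALSE)
  }
  -0.75 * log(1 - (4 / 3) * p)
}

# --- Nei-Gojobori (1986) synonymous/nonsynonymous machinery ---------------

.GC <- Biostrings::GENETIC_CODE
.NTS <- c("A", "C", "G", "T")

codon_aa <- function(codon) .GC[[codon]]

is_stop <- function(codon) identical(.GC[[codon]], "*")

# synonymous site count of one codon: over the 9 single-nt changes, the
# fraction that preserve the amino acid, summed over the 3 positions.
# Changes to stop codons count as nonsynonymous.
codon_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    nt <- substr(codon, pos, pos)
    for (alt in setdiff(.NTS, nt)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (!is_stop(mut) && codon_aa(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# orderings of the single-nucleotide steps; pathways passing through a stop
# codon are excluded (all pathways used if every one hits a stop).
codon_differences <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    idx <- seq_len(nd)
    if (nd == 2L) list(pos[c(1, 2)], pos[c(2, 1)])
    else {
      out <- list()
      for (i in idx) for (j in setdiff(idx, i)) {
        k <- setdiff(idx, c(i, j))
        out[[length(out) + 1L]] <- pos[c(i, j, k)]
      }
      out
    }
  }
  tally <- function(order_pos, allow_stop) {
    cur <- c1; sd <- 0; nd_ <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop(nxt) && !allow_stop) return(NULL)
      if (!is_stop(nxt) && !is_stop(cur) && codon_aa(cur) == codon_aa(nxt)) {
        sd <- sd + 1
      } else {
        nd_ <- nd_ + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd_)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) synonymous divergence with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites per codon from the
#' single-mutation neighbourhood under the standard genetic code, counts
#' synonymous/nonsynonymous differences averaging over all orderings of the
#' changes for codons differing at more than one position, and applies the
#' Jukes-Cantor correction to the proportions. Site counts are averaged over
#' the two sequences.
#'
#' @param seq_a,seq_b gap-free codon-aligned sequences of equal length
#'   (a multiple of 3, no internal stop codons)
#' @return list: `S`, `N` (site counts), `Sd`, `Nd` (differences), `ps`,
#'   `pn`, `Ks`, `Ka` (`Ka` is `NA` when `pn` is saturated)
#' @export
ng86_ks <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("codon alignment lengths differ", call. = FALSE)
  }
  if (grepl("-", paste0(seq_a, seq_b), fixed = TRUE)) {
    stop("gapped codons must be removed before NG86 counting", call. = FALSE)
  }
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  n_cod <- length(ca)
  if (any(vapply(ca[-n_cod], is_stop, TRUE)) ||
      any(vapply(cb[-n_cod], is_stop, TRUE)) ||
      (n_cod > 0 && (is_stop(ca[n_cod]) != is_stop(cb[n_cod])))) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  # terminal stop codons (if both have one) are dropped from the counts
  if (n_cod > 0 && is_stop(ca[n_cod]) && is_stop(cb[n_cod])) {
    ca <- ca[-n_cod]; cb <- cb[-n_cod]; n_cod <- n_cod - 1L
  }
  Sa <- sum(vapply(ca, codon_syn_sites, 0))
  Sb <- sum(vapply(cb, codon_syn_sites, 0))
  S <- (Sa + Sb) / 2
  N <- 3 * n_cod - S
  diffs <- mapply(codon_differences, ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  if (ps >= 0.75) {
    stop("synonymous divergence saturated (ps >= 0.75)", call. = FALSE)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ks = jc_distance(ps),
       Ka = if (pn < 0.75) jc_distance(pn) else NA_real_)
}

#' Remove codons containing gaps from a pair of aligned coding sequences
#' @param seq_a,seq_b aligned sequences of equal length (multiple of 3)
#' @return list with gap-free `a` and `b`
#' @export
strip_gapped_codons <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  ok <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  list(a = paste(ca[ok], collapse = ""), b = paste(cb[ok], collapse = ""))
}

#' Calibrate substitution rates from ortholog synonymous divergence
#'
#' Computes per-gene Ks over a set of codon-aligned ortholog pairs, takes
#' the arithmetic mean, and converts it to a synonymous substitution rate
#' using the species split time: `r_syn = mean(Ks) / T`. The LTR clock is
#' taken as twice the synonymous rate (`r_ltr = 2 * r_syn`), reflecting that
#' retroelement sequences accumulate substitutions about twice as fast as
#' synonymous sites of protein-coding genes. Reported rates round the
#' synonymous rate to 2 significant figures and double it, preserving the
#' exact factor-of-two relation.
#'
#' @param ortholog_pairs list of pairs; each element a list/vector with the
#'   two aligned coding sequences (gapped codons are stripped automatically)
#' @param split_time_years divergence time of the two species in years
#'   (default 42.5 million years)
#' @return list of class `ltr_calibration`: `ks_per_gene`, `mean_ks`,
#'   `split_time_years`, `r_syn`, `r_ltr`, `r_syn_reported`,
#'   `r_ltr_reported`
#' @export
calibrate_rate <- function(ortholog_pairs, split_time_years = 42.5e6) {
  if (length(ortholog_pairs) < 1L) stop("no ortholog pairs", call. = FALSE)
  if (split_time_years <= 0) stop("split time must be positive", call. = FALSE)
  ks <- numeric(0)
  for (pr in ortholog_pairs) {
    g <- strip_gapped_codons(pr[[1]], pr[[2]])
    res <- tryCatch(ng86_ks(g$a, g$b), error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("saturated", conditionMessage(res))) next
      stop(res)
    }
    ks <- c(ks, res$Ks)
  }
  if (length(ks) == 0L) stop("all ortholog pairs saturated", call. = FALSE)
  mean_ks <- mean(ks)
  if (mean_ks == 0) warning("mean Ks is 0; rates are 0", call. = FALSE)
  r_syn <- mean_ks / split_time_years
  structure(list(
    ks_per_gene = ks, mean_ks = mean_ks, split_time_years = split_time_years,
    r_syn = r_syn, r_ltr = 2 * r_syn,
    r_syn_reported = signif(r_syn, 2), r_ltr_reported = 2 * signif(r_syn, 2)),
    class = "ltr_calibration")
}

#' Build a calibration object directly from a mean Ks
#' @param mean_ks mean synonymous divergence
#' @param split_time_years species split time in years
#' @return `ltr_calibration` (see [calibrate_rate()])
#' @export
calibration_from_mean_ks <- function(mean_ks, split_time_years = 42.5e6) {
  r_syn <- mean_ks / split_time_years
  structure(list(
    ks_per_gene = mean_ks, mean_ks = mean_ks,
    split_time_years = split_time_years,
    r_syn = r_syn, r_ltr = 2 * r_syn,
    r_syn_reported = signif(r_syn, 2), r_ltr_reported = 2 * signif(r_syn, 2)),
    class = "ltr_calibration")
}

#' Estimate an element's insertion age from sister-LTR divergence
#'
#' The Jukes-Cantor corrected distance K between the two LTRs is converted
#' to years. Under the default convention (`K_over_r`) the age is
#' `K / r_ltr`: K measures the divergence accumulated between the two LTR
#' copies since insertion and `r_ltr` is the pairwise LTR divergence rate
#' per year. The alternative `K_over_2r` convention (`K / (2 * r_ltr)`),
#' which treats `r_ltr` as a per-lineage rate, is available through
#' `convention`. For identical LTRs (K = 0) the age is 0 and a finite upper
#' bound is reported: the age corresponding to a single substitution over
#' the aligned length, `jc(1 / L) / denominator`.
#'
#' Ages are computed with the calibration's reported rate (2 significant
#' figures), so a printed rate chain reproduces exactly; pass a calibration
#' whose rates are not rounded to change that.
#'
#' @param alignment result of [align_ltr_pair()]
#' @param rates `ltr_calibration` from [calibrate_rate()]
#' @param convention `"K_over_r"` (default) or `"K_over_2r"`
#' @return list: `K`, `age_years`, `age_my`, `zero_div_upper_bound_my`,
#'   `denominator`
#' @export
estimate_age <- function(alignment, rates, convention = c("K_over_r", "K_over_2r")) {
  convention <- match.arg(convention)
  r <- rates$r_ltr_reported %||% rates$r_ltr
  if (r <= 0) stop("LTR substitution rate must be positive", call. = FALSE)
  denom <- if (convention == "K_over_r") r else 2 * r
  K <- jc_distance(alignment$p_distance)
  age <- K / denom
  bound <- NA_real_
  if (K == 0) {
    bound <- jc_distance(1 / alignment$indel_free_cols) / denom / 1e6
  }
  list(K = K, age_years = age, age_my = age / 1e6,
       zero_div_upper_bound_my = bound, denominator = denom)
}

#' Date a whole element set and summarise ages
#'
#' @param ltr5,ltr3 named character vectors of 5' and 3' LTR sequences
#'   (same names, typically from [element_sequences()])
#' @param rates `ltr_calibration`
#' @param superfamily optional named character vector of superfamily calls
#'   used for the per-group summary
#' @param convention age convention passed to [estimate_age()]
#' @return list: `table` (one row per element: `element_id`, `p_distance`,
#'   `K`, `age_my`, `bound_my`), `summary` (mean +/- SE overall and per
#'   superfamily)
#' @export
batch_ages <- function(ltr5, ltr3, rates, superfamily = NULL,
                       convention = c("K_over_r", "K_over_2r")) {
  convention <- match.arg(convention)
  ids <- names(ltr5)
  stopifnot(length(ids) >= 1L, identical(ids, names(ltr3)))
  rows <- lapply(ids, function(id) {
    aln <- align_ltr_pair(ltr5[[id]], ltr3[[id]])
    est <- tryCatch(estimate_age(aln, rates, convention),
                    error = function(e) NULL)
    if (is.null(est)) {
      return(data.frame(element_id = id, p_distance = aln$p_distance,
                        K = NA_real_, age_my = NA_real_, bound_my = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(element_id = id, p_distance = aln$p_distance, K = est$K,
               age_my = est$age_my, bound_my = est$zero_div_upper_bound_my,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  grp <- if (is.null(superfamily)) rep("all", nrow(tab)) else
    unname(superfamily[tab$element_id])
  ok <- !is.na(tab$age_my)
  mk <- function(x) data.frame(n = length(x), mean_age_my = mean(x),
                               se_age_my = se_mean(x))
  summ <- do.call(rbind, lapply(split(tab$age_my[ok], grp[ok]), mk))
  summ <- cbind(group = rownames(summ), summ,
                stringsAsFactors = FALSE)
  overall <- cbind(group = "all", mk(tab$age_my[ok]), stringsAsFactors = FALSE)
  if (!is.null(superfamily)) summ <- rbind(summ, overall)
  else summ <- overall
  rownames(summ) <- NULL
  list(table = tab, summary = summ, convention = convention)
}
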