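# Most-frequent plant codon per amino acid, used to back-translate the
# bundled domain proteins into detectable ORFs.
.BACK_CODON <- c(
  A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGA", H = "CAT", I = "ATT", L = "CTT", K = "AAG",
  M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT", `*` = "TAA")

#' Random DNA sequence with a given GC fraction
#' @param n length
#' @param gc GC fraction
#' @return character scalar
#' @export
random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

back_translate <- function(protein) {
  paste(.BACK_CODON[strsplit(protein, "")[[1]]], collapse = "")
}

# Back-translate with per-call random synonymous codon choice, then add
# point substitutions (repairing any stop codons introduced). Families
# built from the same reference proteins thus share domain content at the
# protein level without sharing long identical DNA stretches -- as real
# retroelement families do. Draws from the current RNG state.
.SYN_CODONS <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

diversified_orf <- function(protein, mut_rate = 0.08) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- .SYN_CODONS[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  dna <- paste(codons, collapse = "")
  v <- strsplit(dna, "")[[1]]
  hit <- which(stats::runif(length(v)) < mut_rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  cods <- substring(paste(v, collapse = ""),
                    seq(1L, length(v), 3L), seq(3L, length(v), 3L))
  stops <- which(vapply(cods, is_stop, TRUE))
  for (i in stops) {
    cods[i] <- sample(setdiff(names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"], cods[i]), 1L)
  }
  paste(cods, collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the simulator emulates: a set of
#' BAC-scale contigs carrying full-length retroelements from 20 families of
#' 5 copies each, with copies of a family placed on distinct contigs (as in
#' BAC assemblies, where contigs rarely carry more than one or two
#' elements), LTRs of 250-800 nt and elements of a few kb, insertion ages
#' uniform over 1-30 MY under an LTR clock of 3.6e-9 substitutions per site
#' per year, 20x uniform shotgun coverage with 100-nt reads at 0.5%
#' substitution error, and 20 ortholog pairs of 120 codons at a target
#' synonymous divergence of 0.077.
#'
#' @param ... named overrides
#' @return named list of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_contigs = 25L,
    contig_len = 50000L,
    gc = 0.38,
    n_families = 20L,
    copies_per_family = 5L,
    solos_per_family = 0L,
    superfamily_mix = c(Copia = 0.65, Gypsy = 0.21, GypsyCHD = 0.14),
    ltr_len_range = c(250L, 800L),
    internal_len_range = c(3000L, 6500L),
    age_range_my = c(1, 30),
    r_ltr = 3.6e-9,
    convention = "K_over_r",
    with_tg_ca = TRUE, with_tsd = TRUE, with_pbs = TRUE, with_ppt = TRUE,
    with_domains = TRUE,
    coverage = 20, read_len = 100L, error_rate = 0.005,
    n_ortholog_pairs = 20L, ortholog_codons = 120L, target_ks = 0.077,
    insertion_margin = 1500L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  stopifnot(cfg$error_rate >= 0, cfg$error_rate < 0.1,
            all(cfg$age_range_my >= 0), cfg$r_ltr > 0)
  structure(cfg, class = "sim_config")
}

#' Build a full-length element template
#'
#' Constructs the ancestral (age-0) element: an LTR beginning TG and ending
#' CA, an internal region carrying, in order, a PBS (reverse complement of
#' a tRNA 3'-end oligo, 1 nt after the 5' LTR), an ORF encoding the
#' superfamily's domain order (Copia: GAG-PR-INT-RT-RH; Gypsy:
#' GAG-PR-RT-RH-INT, optionally followed by a chromodomain), and a purine
#' PPT directly upstream of the 3' LTR. Feature toggles drop individual
#' features. Draws from the current RNG state.
#'
#' @param superfamily `"Copia"`, `"Gypsy"`, or `"GypsyCHD"`
#' @param ltr_len,internal_len template dimensions (nt)
#' @param features named logical list: `tg_ca`, `pbs`, `ppt`, `domains`
#' @param trna_oligos tRNA oligo set (first entry is used)
#' @param library domain library
#' @param gc background GC fraction
#' @return list: `superfamily`, `chromodomain`, `ltr`, `internal`,
#'   `domain_order`, feature toggles
#' @export
build_template <- function(superfamily = "Copia", ltr_len = 400L,
                           internal_len = 4000L,
                           features = list(tg_ca = TRUE, pbs = TRUE,
                                           ppt = TRUE, domains = TRUE),
                           trna_oligos = load_trna_oligos(),
                           library = load_domain_library(),
                           gc = 0.38) {
  chd <- superfamily == "GypsyCHD"
  sf <- if (chd) "Gypsy" else superfamily
  ltr <- random_dna(ltr_len, gc)
  if (isTRUE(features$tg_ca)) {
    substr(ltr, 1L, 2L) <- "TG"
    substr(ltr, ltr_len - 1L, ltr_len) <- "CA"
  } else {
    # make sure the termini are NOT TG/CA so the toggle is meaningful
    if (substr(ltr, 1L, 2L) == "TG") substr(ltr, 1L, 2L) <- "CT"
    if (substr(ltr, ltr_len - 1L, ltr_len) == "CA") {
      substr(ltr, ltr_len - 1L, ltr_len) <- "TC"
    }
  }
  order_labels <- if (sf == "Copia") c("GAG", "PR", "INT", "RT", "RH")
                  else c("GAG", "PR", "RT", "RH", "INT")
  if (chd) order_labels <- c(order_labels, "CHD")
  orf <- ""
  if (isTRUE(features$domains)) {
    prots <- vapply(order_labels, function(lb) {
      library$seq[library$superfamily == sf & library$label == lb][1L]
    }, "")
    if (anyNA(prots)) stop("domain library lacks required label", call. = FALSE)
    orf <- paste0("ATG", paste(vapply(prots, diversified_orf, ""),
                               collapse = ""))
  }
  pbs <- if (isTRUE(features$pbs)) revcomp(trna_oligos[[1L]]) else ""
  ppt <- if (isTRUE(features$ppt)) {
    paste(sample(c("A", "G"), 22L, replace = TRUE, prob = c(0.5, 0.5)),
          collapse = "")
  } else ""
  fixed <- 1L + nchar(pbs) + nchar(orf) + nchar(ppt)
  slack <- internal_len - fixed
  if (slack < 20L) {
    stop(sprintf("internal_len %d too short for requested features (need >= %d)",
                 internal_len, fixed + 20L), call. = FALSE)
  }
  fill1 <- random_dna(slack %/% 2L, gc)
  fill2 <- random_dna(slack - nchar(fill1), gc)
  internal <- paste0(random_dna(1L, gc), pbs, fill1, orf, fill2, ppt)
  stopifnot(nchar(internal) == internal_len)
  list(superfamily = if (chd) "Gypsy" else sf, chromodomain = chd,
       ltr = ltr, internal = internal,
       domain_order = paste(order_labels, collapse = "-"),
       features = features)
}

#' Diverge the two LTRs of a template according to an insertion age
#'
#' Each LTR copy evolves independently under a Jukes-Cantor clock from the
#' shared ancestral LTR. The per-branch expected substitutions per site are
#' set so the expected pairwise divergence K between the two copies matches
#' the dating convention in force: `K = r_ltr * age` under `K_over_r`
#' (each branch gets `r_ltr * age / 2`) or `K = 2 * r_ltr * age` under
#' `K_over_2r`. Per-site difference probability from the ancestor is
#' `(3/4)(1 - exp(-(4/3) * branch))`. Draws from the current RNG state.
#'
#' @param ltr ancestral LTR sequence
#' @param age_years insertion age in years
#' @param r_ltr LTR substitution rate (per site per year)
#' @param convention `"K_over_r"` or `"K_over_2r"`
#' @return list: `ltr5`, `ltr3`, `branch_subs_per_site`, `realized_p`
#'   (observed proportion of differing sites between the two copies)
#' @export
age_ltrs <- function(ltr, age_years, r_ltr = 3.6e-9,
                     convention = c("K_over_r", "K_over_2r")) {
  convention <- match.arg(convention)
  branch <- if (convention == "K_over_r") r_ltr * age_years / 2
            else r_ltr * age_years
  p_site <- 0.75 * (1 - exp(-(4 / 3) * branch))
  mutate <- function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < p_site)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste(v, collapse = "")
  }
  l5 <- mutate(ltr); l3 <- mutate(ltr)
  list(ltr5 = l5, ltr3 = l3, branch_subs_per_site = branch,
       realized_p = hamming(l5, l3) / nchar(ltr))
}

#' Insert element sequences into backbone contigs with TSD formation
#'
#' Each insertion duplicates a 4-6 nt target site: the element lands
#' between two copies of the host sequence at the integration point (the
#' hallmark the detector scores as a TSD). Solo entries (single LTRs, the
#' product of unequal homologous recombination between an element's two
#' LTRs) are inserted the same way and keep one TSD pair. Placement is
#' uniform within each contig, away from the edges, without overlap.
#' Draws from the current RNG state.
#'
#' @param contigs named character vector of backbone contigs
#' @param plan data.frame: one row per insertion with columns `contig`,
#'   `seq` (the sequence to insert), `with_tsd` (logical), plus arbitrary
#'   metadata columns carried into the manifest
#' @param margin minimum distance of insertion points from contig edges
#' @return list: `contigs` (with insertions), `manifest` (plan columns
#'   minus `seq`, plus `start`, `end` (0-based half-open element span,
#'   TSDs excluded) and `tsd`)
#' @export
plant_elements <- function(contigs, plan, margin = 1500L) {
  plan$tsd_len <- ifelse(plan$with_tsd, sample(4:6, nrow(plan), replace = TRUE), 0L)
  plan$start <- NA_integer_; plan$end <- NA_integer_
  plan$tsd <- NA_character_
  for (cid in unique(plan$contig)) {
    rows <- which(plan$contig == cid)
    g <- contigs[[cid]]
    n <- nchar(g)
    lo <- margin; hi <- n - margin
    if (hi - lo < 100L * length(rows)) {
      stop("insufficient space for insertions in contig ", cid, call. = FALSE)
    }
    repeat {
      sites <- sort(sample(lo:hi, length(rows)))
      if (length(sites) < 2L || min(diff(sites)) >= 50L) break
    }
    pieces <- character(0)
    prev <- 0L
    offset <- 0L
    for (j in seq_along(rows)) {
      r <- rows[j]; s <- sites[j]; L <- plan$tsd_len[r]
      pieces <- c(pieces, substr(g, prev + 1L, s + L), plan$seq[r])
      plan$start[r] <- s + L + offset
      plan$end[r] <- plan$start[r] + nchar(plan$seq[r])
      plan$tsd[r] <- if (L > 0L) substr(g, s + 1L, s + L) else ""
      offset <- offset + L + nchar(plan$seq[r])
      prev <- s
    }
    pieces <- c(pieces, substr(g, prev + 1L, n))
    contigs[[cid]] <- paste(pieces, collapse = "")
  }
  manifest <- plan[, setdiff(names(plan), "seq"), drop = FALSE]
  list(contigs = contigs, manifest = manifest)
}

#' Simulate uniform-coverage shotgun reads
#'
#' Uniform start positions across contigs (probability proportional to
#' contig length), both strands equally, i.i.d. substitution errors.
#'
#' @param contigs named character vector
#' @param coverage mean fold-coverage
#' @param read_len read length (nt)
#' @param error_rate per-base substitution error probability
#' @param seed RNG seed
#' @return list: `reads` (named character vector), `origins` (data.frame:
#'   `read_id`, `contig`, `start` 0-based, `strand`)
#' @export
simulate_reads <- function(contigs, coverage, read_len = 100L,
                           error_rate = 0.005, seed = 1L) {
  stopifnot(coverage > 0)
  lens <- nchar(contigs)
  if (read_len > max(lens)) stop("read length exceeds contig length", call. = FALSE)
  usable <- lens >= read_len
  contigs <- contigs[usable]; lens <- lens[usable]
  set.seed(derive_seed(seed, "reads"))
  n_reads <- round(coverage * sum(lens) / read_len)
  ci <- sample.int(length(contigs), n_reads, replace = TRUE,
                   prob = lens - read_len + 1)
  starts <- floor(stats::runif(n_reads) * (lens[ci] - read_len + 1))
  seqs <- character(n_reads)
  for (u in unique(ci)) {
    sel <- ci == u
    seqs[sel] <- substring(contigs[[u]], starts[sel] + 1L, starts[sel] + read_len)
  }
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  rc <- strand == "-"
  if (any(rc)) {
    seqs[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rc])))
  }
  n_err <- stats::rbinom(n_reads, read_len, error_rate)
  for (i in which(n_err > 0L)) {
    v <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(read_len, n_err[i])
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    seqs[i] <- paste(v, collapse = "")
  }
  ids <- sprintf("read%07d", seq_len(n_reads))
  list(reads = stats::setNames(seqs, ids),
       origins = data.frame(read_id = ids, contig = names(contigs)[ci],
                            start = starts, strand = strand,
                            stringsAsFactors = FALSE))
}

#' Simulate codon-aligned ortholog pairs with a target synonymous divergence
#'
#' Generates random stop-free coding sequences and introduces synonymous
#' single-nucleotide substitutions (one per affected codon) so the expected
#' NG86 proportion of synonymous differences matches the target Ks after
#' Jukes-Cantor back-transformation.
#'
#' @param n_pairs number of ortholog pairs
#' @param n_codons codons per sequence
#' @param target_ks target synonymous divergence (JC-corrected)
#' @param seed RNG seed
#' @return list of pairs; each a list with sequences `a`, `b`
#' @export
simulate_orthologs <- function(n_pairs = 20L, n_codons = 120L,
                               target_ks = 0.077, seed = 1L) {
  if (target_ks < 0) stop("negative target Ks", call. = FALSE)
  target_ps <- 0.75 * (1 - exp(-(4 / 3) * target_ks))
  if (target_ps >= 0.75) stop("target Ks beyond saturation", call. = FALSE)
  set.seed(derive_seed(seed, "orthologs"))
  codons <- apply(expand.grid(.NTS, .NTS, .NTS), 1L, paste, collapse = "")
  codons <- codons[!vapply(codons, is_stop, TRUE)]
  pairs <- vector("list", n_pairs)
  for (pi in seq_len(n_pairs)) {
    ca <- sample(codons, n_codons, replace = TRUE)
    S <- sum(vapply(ca, codon_syn_sites, 0))
    n_changes <- round(target_ps * S)
    # synonymous single-change options per codon
    opts <- lapply(ca, function(cod) {
      res <- list()
      for (pos in 1:3) for (alt in setdiff(.NTS, substr(cod, pos, pos))) {
        mut <- cod; substr(mut, pos, pos) <- alt
        if (!is_stop(mut) && codon_aa(mut) == codon_aa(cod)) {
          res[[length(res) + 1L]] <- c(pos = pos, alt = alt)
        }
      }
      res
    })
    capable <- which(lengths(opts) > 0L)
    if (n_changes > length(capable)) {
      stop("target Ks infeasible at this sequence length", call. = FALSE)
    }
    cb <- ca
    for (i in capable[sample.int(length(capable), n_changes)]) {
      ch <- opts[[i]][[sample.int(length(opts[[i]]), 1L)]]
      cod <- cb[i]
      substr(cod, as.integer(ch[["pos"]]), as.integer(ch[["pos"]])) <- ch[["alt"]]
      cb[i] <- cod
    }
    pairs[[pi]] <- list(a = paste(ca, collapse = ""),
                        b = paste(cb, collapse = ""))
  }
  pairs
}

#' Simulate a genome of contigs with planted retroelement families
#'
#' Orchestrates template construction, LTR aging, and insertion into
#' backbone contigs; copies of the same family are placed on distinct
#' contigs. Produces the ground-truth manifest used to score detection,
#' classification, dating and solo-LTR statistics.
#'
#' @param cfg [sim_config()]
#' @return list: `contigs`, `manifest` (per planted copy: coordinates,
#'   family, superfamily, age, TSD, solo flag, realized LTR divergence),
#'   `templates`
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(derive_seed(cfg$seed, "genome"))
  contigs <- stats::setNames(
    vapply(seq_len(cfg$n_contigs), function(i) random_dna(cfg$contig_len, cfg$gc), ""),
    sprintf("contig%03d", seq_len(cfg$n_contigs)))
  trna <- load_trna_oligos()
  lib <- load_domain_library()
  features <- list(tg_ca = cfg$with_tg_ca, pbs = cfg$with_pbs,
                   ppt = cfg$with_ppt, domains = cfg$with_domains)
  templates <- vector("list", cfg$n_families)
  plan_rows <- list()
  mix <- cfg$superfamily_mix / sum(cfg$superfamily_mix)
  for (f in seq_len(cfg$n_families)) {
    sf <- sample(names(mix), 1L, prob = mix)
    pick <- function(a, b) if (a >= b) as.integer(a) else sample(a:b, 1L)
    ltr_len <- pick(cfg$ltr_len_range[1], cfg$ltr_len_range[2])
    min_internal <- max(cfg$internal_len_range[1],
                        if (cfg$with_domains) 2500L else 100L)
    internal_len <- pick(min_internal, cfg$internal_len_range[2])
    tpl <- build_template(sf, ltr_len, internal_len, features, trna, lib, cfg$gc)
    templates[[f]] <- tpl
    n_ins <- cfg$copies_per_family + cfg$solos_per_family
    target_contigs <- sample(names(contigs),
                             min(n_ins, cfg$n_contigs), replace = n_ins > cfg$n_contigs)
    target_contigs <- rep_len(target_contigs, n_ins)
    for (cpy in seq_len(n_ins)) {
      solo <- cpy > cfg$copies_per_family
      age_my <- stats::runif(1L, cfg$age_range_my[1], cfg$age_range_my[2])
      aged <- age_ltrs(tpl$ltr, age_my * 1e6, cfg$r_ltr, cfg$convention)
      seqv <- if (solo) aged$ltr5
              else paste0(aged$ltr5, tpl$internal, aged$ltr3)
      plan_rows[[length(plan_rows) + 1L]] <- data.frame(
        contig = target_contigs[cpy], seq = seqv, with_tsd = cfg$with_tsd,
        family = sprintf("FAM%02d", f), superfamily = tpl$superfamily,
        chromodomain = tpl$chromodomain, solo = solo,
        age_my = age_my, ltr_len = ltr_len,
        realized_p = if (solo) NA_real_ else aged$realized_p,
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, plan_rows)
  planted <- plant_elements(contigs, plan, cfg$insertion_margin)
  planted$manifest <- planted$manifest[order(planted$manifest$contig,
                                             planted$manifest$start), ]
  rownames(planted$manifest) <- NULL
  list(contigs = planted$contigs, manifest = planted$manifest,
       templates = templates, config = cfg)
}
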