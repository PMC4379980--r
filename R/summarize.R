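#' Genome equivalents represented by a clone library
#'
#' `coverage = n_clones * mean_insert / genome_size`, reported truncated
#' (floored) to one decimal. Truncation rather than rounding is deliberate:
#' it is the conservative convention for library coverage (a library
#' "represents" only whole tenths of a genome equivalent actually attained).
#'
#' @param n_clones number of clones
#' @param mean_insert mean insert size in nt
#' @param genome_size haploid genome size in nt
#' @return coverage, truncated to 1 decimal
#' @export
genome_equivalents <- function(n_clones, mean_insert, genome_size) {
  if (genome_size <= 0) stop("genome size must be positive", call. = FALSE)
  if (n_clones < 0 || mean_insert < 0) stop("inputs must be non-negative", call. = FALSE)
  floor(n_clones * mean_insert / genome_size * 10) / 10
}

#' Per-superfamily summary statistics
#'
#' Mean and standard error (sd / sqrt(n); 0 for n = 1) of element length,
#' LTR lengths, redundancy and age, grouped by superfamily.
#'
#' @param elements element table carrying `superfamily` plus any of the
#'   columns `length_nt`, `ltr5_len`, `ltr3_len`, `reads_per_kb`, `age_my`
#' @return data.frame, one row per superfamily plus a `Total` row: `n` and
#'   `mean_*` / `se_*` per available statistic
#' @export
superfamily_table <- function(elements) {
  stats_cols <- intersect(c("length_nt", "ltr5_len", "ltr3_len",
                            "reads_per_kb", "age_my"), names(elements))
  groups <- split(elements, elements$superfamily)
  one <- function(df, name) {
    row <- data.frame(superfamily = name, n = nrow(df),
                      stringsAsFactors = FALSE)
    for (cc in stats_cols) {
      x <- df[[cc]][!is.na(df[[cc]])]
      row[[paste0("mean_", cc)]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0("se_", cc)]] <- if (length(x)) se_mean(x) else NA_real_
    }
    row
  }
  out <- do.call(rbind, lapply(names(groups), function(g) one(groups[[g]], g)))
  out <- rbind(out, one(elements, "Total"))
  rownames(out) <- NULL
  out
}

.FLANK_CLASSES <- c("Gene", "Transposon", "Unclassified")

#' Tabulate the flanking-sequence context of an element set
#'
#' Cross-tabulates upstream vs downstream flank classes (Gene, Transposon,
#' Unclassified) with exact percentages to two decimals, and derives the
#' aggregate counts of interest: elements near a gene on either side,
#' elements adjacent to a transposon on either side, and elements flanked
#' by transposon sequence on both sides (candidate nested-insertion loci).
#' Flank labelling itself comes from annotations or simulator truth; this
#' function only tabulates.
#'
#' @param flanks data.frame with columns `upstream` and `downstream`, each
#'   one of `"Gene"`, `"Transposon"`, `"Unclassified"`; or a named vector
#'   of counts for the 9 ordered combinations
#' @return list: `table` (rows: upstream, downstream, count, percentage),
#'   `total`, `near_gene` (count + pct), `transposon_adjacent`,
#'   `both_transposon`
#' @export
flank_context_table <- function(flanks) {
  if (is.data.frame(flanks)) {
    bad <- setdiff(unique(c(flanks$upstream, flanks$downstream)), .FLANK_CLASSES)
    if (length(bad) > 0) {
      stop("unknown flank class: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    counts <- table(factor(flanks$upstream, .FLANK_CLASSES),
                    factor(flanks$downstream, .FLANK_CLASSES))
    grid <- expand.grid(upstream = .FLANK_CLASSES, downstream = .FLANK_CLASSES,
                        stringsAsFactors = FALSE)
    grid$count <- mapply(function(u, d) counts[u, d],
                         grid$upstream, grid$downstream)
  } else {
    grid <- expand.grid(upstream = .FLANK_CLASSES, downstream = .FLANK_CLASSES,
                        stringsAsFactors = FALSE)
    if (length(flanks) != 9L) stop("expected 9 counts", call. = FALSE)
    grid$count <- as.integer(flanks)
  }
  total <- sum(grid$count)
  grid$percentage <- round(100 * grid$count / total, 2)
  grid <- grid[grid$count > 0 | total == 0, , drop = FALSE]
  agg <- function(sel) {
    n <- sum(grid$count[sel])
    list(count = n, pct = round(100 * n / total, 2))
  }
  list(
    table = grid,
    total = total,
    near_gene = agg(grid$upstream == "Gene" | grid$downstream == "Gene"),
    transposon_adjacent = agg(grid$upstream == "Transposon" |
                              grid$downstream == "Transposon"),
    both_transposon = agg(grid$upstream == "Transposon" &
                          grid$downstream == "Transposon"))
}

#' Bin insertion ages into a histogram
#'
#' Half-open bins `[k*w, (k+1)*w)` in million years, overall and per
#' superfamily.
#'
#' @param ages numeric vector of ages (MY), non-negative
#' @param superfamily optional grouping vector aligned with `ages`
#' @param bin_width bin width in MY (default 1)
#' @return data.frame: `bin_start`, `bin_end`, `group`, `count`
#' @export
age_histogram <- function(ages, superfamily = NULL, bin_width = 1) {
  if (length(ages) == 0L) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      group = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (any(ages < 0, na.rm = TRUE)) stop("negative age", call. = FALSE)
  ok <- !is.na(ages)
  ages <- ages[ok]
  grp <- if (is.null(superfamily)) rep("all", length(ages)) else
    as.character(superfamily)[ok]
  bin <- floor(ages / bin_width)
  levels_bin <- 0:max(bin)
  out <- list()
  for (g in unique(c(grp, "all"))) {
    x <- if (g == "all") bin else bin[grp == g]
    tab <- table(factor(x, levels = levels_bin))
    out[[g]] <- data.frame(bin_start = levels_bin * bin_width,
                           bin_end = (levels_bin + 1) * bin_width,
                           group = g, count = as.integer(tab),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pair insertion ages with redundancy and compute their rank correlation
#'
#' @param ages named numeric vector (element id -> age in MY)
#' @param rpk named numeric vector (element id -> reads per kb)
#' @return list: `table` (element_id, age_my, reads_per_kb), `spearman`
#'   (rank correlation; 0 with `note = "ties"` when either variable is
#'   constant), `note`
#' @export
age_redundancy_table <- function(ages, rpk) {
  if (!setequal(names(ages), names(rpk))) {
    stop("mismatched element ids between ages and redundancy", call. = FALSE)
  }
  ids <- names(ages)
  tab <- data.frame(element_id = ids, age_my = unname(ages),
                    reads_per_kb = unname(rpk[ids]), stringsAsFactors = FALSE)
  note <- NA_character_
  if (stats::sd(tab$age_my) == 0 || stats::sd(tab$reads_per_kb) == 0) {
    rho <- 0
    note <- "ties"
  } else {
    rho <- stats::cor(tab$age_my, tab$reads_per_kb, method = "spearman")
  }
  list(table = tab, spearman = rho, note = note)
}
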