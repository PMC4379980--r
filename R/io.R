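#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that enforces the
#' package's sequence-record invariants: unique non-empty ids, non-empty
#' sequences, uppercase residues. Input order is preserved and CRLF line
#' endings are tolerated.
#'
#' @param path path to a FASTA file
#' @param type `"DNA"` (validated against the A/C/G/T/N alphabet) or
#'   `"protein"` (no alphabet check beyond uppercase)
#' @return named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header, with the full header
#'   kept in the `"description"` attribute
#' @export
read_fasta <- function(path, type = c("DNA", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("FASTA file has no records: ", path, call. = FALSE)
  full <- names(ss)
  ids <- vapply(strsplit(full, "[ \t]+"), `[`, "", 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  if (type == "DNA") {
    for (i in seq_along(seqs)) assert_dna(seqs[i], ids[i])
  }
  out <- stats::setNames(seqs, ids)
  attr(out, "description") <- stats::setNames(full, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    cat(paste0(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               collapse = "\n"), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read short reads from FASTA or FASTQ
#'
#' FASTQ qualities are ignored; the mapper is identity-based.
#'
#' @param path FASTA or FASTQ file (auto-detected from the first character)
#' @return named character vector of uppercase read sequences
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path, call. = FALSE)
  first <- readChar(path, 1L)
  if (identical(first, "@")) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    ids <- vapply(strsplit(names(ss), "[ \t]+"), `[`, "", 1L)
    stats::setNames(toupper(as.character(ss)), ids)
  } else {
    read_fasta(path, type = "DNA")
  }
}

# GFF3 feature types used for element parts
.GFF_TYPES <- c(
  element = "LTR_retrotransposon",
  ltr = "long_terminal_repeat",
  tsd = "target_site_duplication",
  pbs = "primer_binding_site",
  ppt = "RR_tract"
)

#' Write detected elements as GFF3
#'
#' Each element becomes a `LTR_retrotransposon` feature with child
#' `long_terminal_repeat` features (and `primer_binding_site` / `RR_tract`
#' children where detected), linked through `ID`/`Parent` attributes.
#' Internal 0-based half-open coordinates are converted to the GFF3 1-based
#' inclusive convention.
#'
#' @param elements element table as returned by [scan_contigs()]
#' @param path output path
#' @param contig_lengths optional named vector used to bound-check intervals
#' @return `path`, invisibly
#' @export
write_gff3 <- function(elements, path, contig_lengths = NULL) {
  rows <- list()
  add <- function(contig, type, s0, e0, strand, id, parent = NA_character_) {
    if (!is.null(contig_lengths) && contig %in% names(contig_lengths)) {
      if (s0 < 0 || e0 > contig_lengths[[contig]]) {
        stop(sprintf("interval [%d,%d) out of bounds on %s", s0, e0, contig),
             call. = FALSE)
      }
    }
    attrs <- paste0("ID=", id)
    if (!is.na(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = contig, source = "ltrpipe", type = type,
      start = s0 + 1L, end = e0, score = ".", strand = strand,
      phase = ".", attributes = attrs, stringsAsFactors = FALSE)
  }
  if (nrow(elements) > 0) {
    for (i in seq_len(nrow(elements))) {
      el <- elements[i, ]
      eid <- el$element_id
      add(el$contig, .GFF_TYPES[["element"]], el$start, el$end, el$strand, eid)
      add(el$contig, .GFF_TYPES[["ltr"]], el$ltr5_start, el$ltr5_end,
          el$strand, paste0(eid, "_LTR5"), eid)
      add(el$contig, .GFF_TYPES[["ltr"]], el$ltr3_start, el$ltr3_end,
          el$strand, paste0(eid, "_LTR3"), eid)
      if (!is.na(el$pbs_start)) {
        add(el$contig, .GFF_TYPES[["pbs"]], el$pbs_start, el$pbs_end,
            el$strand, paste0(eid, "_PBS"), eid)
      }
      if (!is.na(el$ppt_start)) {
        add(el$contig, .GFF_TYPES[["ppt"]], el$ppt_start, el$ppt_end,
            el$strand, paste0(eid, "_PPT"), eid)
      }
      if (!is.na(el$tsd) && nzchar(el$tsd)) {
        add(el$contig, .GFF_TYPES[["tsd"]], el$start - nchar(el$tsd), el$start,
            el$strand, paste0(eid, "_TSD5"), eid)
        add(el$contig, .GFF_TYPES[["tsd"]], el$end, el$end + nchar(el$tsd),
            el$strand, paste0(eid, "_TSD3"), eid)
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  cat("##gff-version 3\n", file = con)
  if (length(rows) > 0) {
    tab <- do.call(rbind, rows)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an element GFF3 back into an element table
#'
#' Inverse of [write_gff3()] for the features that file writes; used for
#' round-trip checks and for feeding detector output to downstream stages.
#'
#' @param path GFF3 file
#' @return data.frame with the coordinate columns of the element table
#'   (0-based half-open)
#' @export
read_gff3_elements <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  getattr <- function(x, f) if (f %in% names(S4Vectors::mcols(x))) S4Vectors::mcols(x)[[f]] else NULL
  ids <- df$ID
  parents <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  is_el <- df$type == .GFF_TYPES[["element"]]
  out <- data.frame(
    element_id = ids[is_el],
    contig = as.character(df$seqnames[is_el]),
    start = df$start[is_el] - 1L,
    end = df$end[is_el],
    strand = as.character(df$strand[is_el]),
    stringsAsFactors = FALSE)
  pick <- function(suffix) {
    idx <- match(paste0(out$element_id, suffix), ids)
    list(start = df$start[idx] - 1L, end = df$end[idx])
  }
  l5 <- pick("_LTR5"); l3 <- pick("_LTR3")
  pbs <- pick("_PBS"); ppt <- pick("_PPT")
  out$ltr5_start <- l5$start; out$ltr5_end <- l5$end
  out$ltr3_start <- l3$start; out$ltr3_end <- l3$end
  out$pbs_start <- pbs$start; out$pbs_end <- pbs$end
  out$ppt_start <- ppt$start; out$ppt_end <- ppt$end
  tsd5 <- pick("_TSD5")
  out$tsd_len <- ifelse(is.na(tsd5$start), NA_integer_, tsd5$end - tsd5$start)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Write a data frame as TSV
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
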