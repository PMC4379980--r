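#' Build a run configuration
#'
#' All pipeline thresholds in one flat, serializable list. Every default is
#' documented here and mirrored by the stage functions; the whole set can be
#' audited or overridden through a flat `key = value` text file
#' ([read_config()] / [write_config()]).
#'
#' Detector defaults: contigs shorter than `min_contig_len` (10,000 nt) are
#' skipped; LTRs of 100-3,500 nt; elements of 1,000-16,000 nt; sister-LTR
#' identity at least 0.80; 13-mer seeds; TG/CA boundary snapping within
#' +/- 25 nt. Mapper defaults follow the redundancy protocol: reads cut to
#' 75 nt, minimum identity 0.90, minimum length fraction 0.90, multireads
#' assigned uniformly at random from the seeded stream. Dating defaults:
#' ortholog split time 42.5 MY; the LTR clock is twice the synonymous rate;
#' ages are divergence / rate (`K_over_r`), with `K_over_2r` available.
#'
#' @param ... named overrides of any default
#' @return object of class `ltr_config` (a named list)
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # detector
    min_contig_len = 10000L,
    min_ltr_len = 100L,
    max_ltr_len = 3500L,
    min_elem_len = 1000L,
    max_elem_len = 16000L,
    min_ltr_similarity = 0.80,
    seed_kmer_len = 13L,
    boundary_snap_window = 25L,
    missing_features_allowed = 1L,
    pbs_window = 30L,
    pbs_max_mismatches = 2L,
    ppt_window = 40L,
    ppt_min_purine = 0.80,
    # classifier
    domain_score_min = 55,
    reclass_min_len = 400L,
    reclass_min_identity = 0.80,
    # dating
    split_time_years = 42.5e6,
    age_convention = "K_over_r",
    # mapper
    min_identity = 0.90,
    min_length_fraction = 0.90,
    read_truncate_len = 75L,
    map_kmer_len = 15L,
    solo_ratio_threshold = 2.5,
    # phylogeny
    min_rt_aa = 80L,
    family_cutoff = 0.25,
    bootstrap_replicates = 100L
  )
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("config overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "ltr_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$min_ltr_len < cfg$max_ltr_len, "min_ltr_len must be < max_ltr_len")
  chk(cfg$min_elem_len < cfg$max_elem_len, "min_elem_len must be < max_elem_len")
  chk(cfg$min_ltr_similarity > 0 && cfg$min_ltr_similarity <= 1,
      "min_ltr_similarity must be in (0,1]")
  chk(cfg$min_identity > 0 && cfg$min_identity <= 1,
      "min_identity must be in (0,1]")
  chk(cfg$min_length_fraction > 0 && cfg$min_length_fraction <= 1,
      "min_length_fraction must be in (0,1]")
  chk(cfg$ppt_min_purine > 0 && cfg$ppt_min_purine <= 1,
      "ppt_min_purine must be in (0,1]")
  chk(cfg$split_time_years > 0, "split_time_years must be positive")
  chk(cfg$age_convention %in% c("K_over_r", "K_over_2r"),
      "age_convention must be K_over_r or K_over_2r")
  invisible(cfg)
}

#' Write a configuration as flat key = value text
#' @param cfg `ltr_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, format(v, scientific = FALSE, trim = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration file; absent keys take the documented defaults
#' @param path key = value text file
#' @return `ltr_config`
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  defaults <- run_config()
  parsed <- lapply(seq_along(keys), function(i) {
    proto <- defaults[[keys[i]]]
    if (is.null(proto)) stop("unknown config key: ", keys[i], call. = FALSE)
    if (is.character(proto)) vals[i]
    else if (is.integer(proto)) as.integer(vals[i])
    else as.numeric(vals[i])
  })
  do.call(run_config, stats::setNames(parsed, keys))
}
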