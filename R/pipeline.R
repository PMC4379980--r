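#' ltrpipe: structural annotation, dating and redundancy analysis of LTR
#' retrotransposons
#'
#' End-to-end pipeline for full-length LTR retroelement analysis in
#' assembled contigs: structural detection (paired LTRs, TG...CA termini,
#' TSD, PBS, PPT), Copia/Gypsy classification from protein-domain order,
#' insertion-age dating from sister-LTR divergence under a calibrated
#' Jukes-Cantor clock, read-mapping redundancy and solo-LTR ratios, an RT
#' neighbour-joining phylogeny, and a ground-truth simulator.
#'
#' @name ltrpipe-package
#' @keywords internal
"_PACKAGE"

#' Run the full pipeline on a set of inputs
#'
#' Chains detect, classify, date, map, phylo and report stages, writing all
#' artifacts (GFF3, FASTA, TSV tables, newick tree) into `out_dir`.
#' Identical inputs, configuration and seed yield byte-identical outputs.
#' A stage failure aborts with the stage name and cause.
#'
#' @param config [run_config()] (its `seed` drives all stochastic steps)
#' @param contigs named character vector of contig sequences
#' @param reads optional named character vector of reads; mapping stages
#'   are skipped when absent
#' @param orthologs optional list of codon-aligned ortholog pairs for rate
#'   calibration; when absent, rates come from `mean_ks` (below)
#' @param out_dir output directory (created if needed)
#' @param mean_ks fallback mean synonymous divergence used when no
#'   ortholog pairs are supplied (default 0.077)
#' @return invisible list with the main in-memory results: `elements`,
#'   `ages`, `calibration`, `redundancy`, `tree`, `families`, `summary`
#' @export
run_pipeline <- function(config, contigs, reads = NULL, orthologs = NULL,
                         out_dir = ".", mean_ks = 0.077) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  elements <- stage("detect", scan_contigs(contigs, config))
  if (nrow(elements) == 0L) {
    warning("no elements detected; writing empty element table", call. = FALSE)
    write_tsv(elements, file.path(out_dir, "elements.tsv"))
    write_gff3(elements, file.path(out_dir, "elements.gff3"))
    return(invisible(list(elements = elements)))
  }
  seqs <- element_sequences(elements, contigs)

  elements <- stage("classify", classify_elements(elements, seqs,
                                                  config = config))
  elements$length_nt <- elements$end - elements$start
  elements$ltr5_len <- elements$ltr5_end - elements$ltr5_start
  elements$ltr3_len <- elements$ltr3_end - elements$ltr3_start

  calibration <- stage("calibrate", {
    if (!is.null(orthologs)) calibrate_rate(orthologs, config$split_time_years)
    else calibration_from_mean_ks(mean_ks, config$split_time_years)
  })

  ages <- stage("date", batch_ages(
    seqs$ltr5, seqs$ltr3, calibration,
    superfamily = stats::setNames(elements$superfamily, elements$element_id),
    convention = config$age_convention))
  elements$age_my <- ages$table$age_my[match(elements$element_id,
                                             ages$table$element_id)]

  redundancy <- NULL
  if (!is.null(reads) && length(reads) > 0) {
    redundancy <- stage("map", element_redundancy(elements, seqs, reads,
                                                  config, seed = config$seed))
    elements$reads_per_kb <- redundancy$reads_per_kb[
      match(elements$element_id, redundancy$element_id)]
  }

  tree <- NULL; families <- NULL
  rt <- stage("phylo", extract_rt(elements, seqs, config = config))
  if (length(rt) >= 3L) {
    d <- stage("phylo", protein_distances(rt))
    tree <- stage("phylo", nj_tree(d))
    families <- stage("phylo", family_clusters(d, config$family_cutoff))
  }

  summary_tab <- stage("report", superfamily_table(elements))
  hist_tab <- stage("report", age_histogram(
    elements$age_my, elements$superfamily))

  # artifacts
  write_tsv(elements[, setdiff(names(elements), "element_sequence")],
            file.path(out_dir, "elements.tsv"))
  write_gff3(elements, file.path(out_dir, "elements.gff3"),
             contig_lengths = nchar(contigs))
  write_fasta(seqs$element, file.path(out_dir, "elements.fasta"))
  age_hdr <- file.path(out_dir, "ages.tsv")
  writeLines(sprintf("# age convention: %s; r_ltr = %s subs/site/year (alternative K_over_2r ages are half/twice accordingly)",
                     config$age_convention,
                     format(calibration$r_ltr, digits = 3)), age_hdr)
  suppressWarnings(utils::write.table(ages$table, age_hdr, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  write_tsv(data.frame(mean_ks = calibration$mean_ks,
                       split_time_years = calibration$split_time_years,
                       r_syn = calibration$r_syn,
                       r_ltr = calibration$r_ltr,
                       r_syn_reported = calibration$r_syn_reported,
                       r_ltr_reported = calibration$r_ltr_reported),
            file.path(out_dir, "calibration.tsv"))
  if (!is.null(redundancy)) {
    write_tsv(redundancy, file.path(out_dir, "redundancy.tsv"))
  }
  if (!is.null(tree)) {
    write_newick(tree, file.path(out_dir, "rt_tree.nwk"))
    write_tsv(families, file.path(out_dir, "families.tsv"))
  }
  write_tsv(summary_tab, file.path(out_dir, "superfamily_summary.tsv"))
  write_tsv(hist_tab, file.path(out_dir, "age_histogram.tsv"))

  invisible(list(elements = elements, ages = ages, calibration = calibration,
                 redundancy = redundancy, tree = tree, families = families,
                 summary = summary_tab))
}
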