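# Shared simulation fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small clean genome: identical LTRs, all features planted
clean_sim <- function() {
  fixture("clean_sim", function() {
    cfg <- sim_config(seed = 101, n_contigs = 5, contig_len = 25000,
                      n_families = 3, copies_per_family = 2,
                      age_range_my = c(0, 0),
                      internal_len_range = c(2600, 4000))
    simulate_genome(cfg)
  })
}

clean_detection <- function() {
  fixture("clean_detection", function() {
    suppressWarnings(scan_contigs(clean_sim()$contigs, run_config()))
  })
}

clean_classified <- function() {
  fixture("clean_classified", function() {
    det <- clean_detection()
    seqs <- element_sequences(det, clean_sim()$contigs)
    list(elements = classify_elements(det, seqs), seqs = seqs)
  })
}

# match detected elements to manifest truth rows by contig + proximity
match_truth <- function(det, manifest, tol = 200) {
  m <- manifest[!manifest$solo, , drop = FALSE]
  merged <- merge(m, det, by = "contig", suffixes = c(".truth", ".det"))
  merged[abs(merged$start.truth - merged$start.det) < tol, , drop = FALSE]
}

# one-family genome + reads for ratio statistics
ratio_fixture <- function(S, seed) {
  cfg <- sim_config(seed = seed, n_contigs = 6, contig_len = 30000,
                    n_families = 1, copies_per_family = 10,
                    solos_per_family = S, ltr_len_range = c(300L, 300L),
                    internal_len_range = c(1400L, 1400L),
                    with_domains = FALSE, age_range_my = c(0, 0),
                    coverage = 20, read_len = 100L, error_rate = 0.005)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim$contigs, cfg$coverage, cfg$read_len,
                       cfg$error_rate, seed)
  m <- sim$manifest[!sim$manifest$solo, ][1, ]
  g <- sim$contigs[[m$contig]]
  list(
    ltr5 = substr(g, m$start + 1, m$start + m$ltr_len),
    internal = substr(g, m$start + m$ltr_len + 1, m$end - m$ltr_len),
    reads = truncate_reads(rd$reads, 75))
}

# sampling sd of a count ratio treating both counts as Poisson
ratio_sd <- function(st) {
  st$ratio * sqrt(1 / st$n_ltr + 1 / st$n_inter)
}
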