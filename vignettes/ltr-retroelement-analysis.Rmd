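---
title: "Detecting, classifying and dating LTR retroelements with ltrpipe"
author: "ltrpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, classifying and dating LTR retroelements with ltrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrpipe)
```

## The problem

LTR retrotransposons are the dominant repeat class of most plant genomes.
A full-length element consists of two long terminal repeats (LTRs) flanking
an internal region that encodes the retroviral-like polyprotein
(GAG, protease, integrase, reverse transcriptase, RNaseH). Integration
leaves a 4-6 nt target-site duplication (TSD) on both sides; reverse
transcription is primed by a tRNA annealing to a 15-18 nt primer-binding
site (PBS) just inside the 5' LTR and by a 20-25 nt polypurine tract (PPT)
directly upstream of the 3' LTR. Two biological clocks make these elements
dateable and countable:

* the two LTRs are identical at insertion and diverge neutrally afterwards,
  so their corrected distance measures the insertion age;
* unequal homologous recombination between the two LTRs excises the
  internal region and leaves a **solo LTR**, so the coverage ratio between
  LTR and internal sequence in shotgun reads measures how much of a family
  has been lost.

`ltrpipe` implements the full chain -- structural detection in assembled
contigs, Copia/Gypsy classification by protein-domain order, rate
calibration from ortholog synonymous divergence, insertion-age dating,
read-mapping redundancy with the solo-LTR ratio statistic, and an RT-domain
neighbour-joining phylogeny -- together with an insertion simulator that
provides ground truth for every stage.

## Structural detection

Contigs shorter than 10,000 nt are skipped: shorter sequences cannot hold a
full-length element plus informative flanks. Within a contig, exact 13-mer
matches between distinct regions are grouped by diagonal into collinear
chains; a chain is promoted to an LTR-pair candidate when the implied LTR
length lies in 100-3,500 nt, the element span in 1,000-16,000 nt, and the
global-alignment identity of the two repeats is at least 0.80. These bounds
are deliberately generous around reported plant LTR dimensions (mean LTR
lengths near 540-650 nt and element lengths near 5.6-7.6 kb) and are all
configurable through `run_config()`.

Candidate boundaries are then refined in two steps. First the two LTR
neighbourhoods are realigned with the Smith-Waterman algorithm using a
stringent scoring matrix (match +1, mismatch -2): with these scores two
unrelated sequences have negative expected score even under skewed base
composition, so the local alignment cannot drift past the true homology
ends -- an issue we observed with a +2/-1 matrix, where the purine-rich PPT
would align against AT-rich host flanks and push the proposed boundary
~30 nt too far. Second, the termini are snapped to the canonical TG (LTR
starts) / CA (LTR ends) dinucleotides within +/- 25 nt, using one common
offset per terminus pair so the two LTRs stay length-compatible. When no
TG/CA pair is in reach the realigned extents are kept, the element is
flagged `has_tg_ca = FALSE`, and a last-resort re-anchoring searches small
joint offsets of the element span for a shared 4-6-mer flank (the TSD);
this rescues elements whose terminal dinucleotides have mutated away.

TSD, PBS and PPT detection are deterministic scans: the longest exact
4-6-mer shared by the immediate flanks; a 15-18-nt match (at most 2
mismatches) to the reverse complement of a bundled tRNA 3'-end oligo within
30 nt of the 5' LTR; and the highest-purine 20-25-nt window (fraction
>= 0.80) within 40 nt of the 3' LTR. An element is reported when at most
one of the four features {TG...CA, TSD, PBS, PPT} is missing -- genuine
elements occasionally lack one.

Direct repeats are orientation-symmetric, so one forward scan covers
elements inserted on either strand; the transcriptional strand is assigned
later from the protein-domain reading frames. Nested insertions are not
resolved: overlapping candidate spans are reduced to the highest-identity
one per locus.

## Superfamily classification

The internal region is translated in six frames and searched with
Smith-Waterman (BLOSUM62, gap open 11 / extend 1) against a bundled domain
library (GAG, PR, INT, RT, RH, CHD; one Copia-like and one Gypsy-like
variant each). Hits scoring at least 55 are kept -- a raw-score threshold
replaces database E-values because the library is small and fixed, which
keeps the search deterministic. The superfamily call uses the
integrase-position rule: INT upstream of RT is Copia, INT downstream of
RNaseH is Gypsy, and a chromodomain hit downstream of INT marks the
chromodomain-bearing Gypsy subgroup. Elements with neither RT nor INT are
`Unknown`; a second pass rescues unknowns that align to a classified
element over >= 400 nt at >= 80% nucleotide identity, inheriting its
superfamily. The bundled library is a constructed stand-in (see
`load_domain_library()`), so per-element calls on real data depend on the
library the user supplies.

## Rate calibration and insertion-age dating

Synonymous divergence is computed with the Nei-Gojobori (1986) method:
synonymous site counts per codon from the single-mutation neighbourhood
under the standard code, difference counts averaged over all orderings of
the changes in multi-difference codons, and the Jukes-Cantor correction
`K = -(3/4) ln(1 - (4/3) p)` applied to the proportions. Changes that
create a stop codon are counted as nonsynonymous, and mutational pathways
passing through a stop are excluded unless every pathway does; this is the
common treatment and the one our brute-force pathway oracle verifies.

`calibrate_rate()` averages per-gene Ks over ortholog pairs (mean of Ks,
not a concatenation, matching how a mean synonymous divergence is usually
reported) and divides by the species split time, 42.5 million years by
default for the olive/ash calibration the defaults emulate. The LTR clock
is twice the synonymous rate, `r_ltr = 2 r_syn`, reflecting the roughly
two-fold faster substitution accumulation observed in retroelements
relative to synonymous sites of genes. With a mean Ks of 0.077 this chain
yields `r_syn = 1.8e-9` and `r_ltr = 3.6e-9` substitutions/site/year.
Reported rates round the synonymous rate to two significant figures and
double it (so the factor-of-two relation is preserved exactly), and ages
are computed with the reported rate -- the convention a printed rate chain
implies; the unrounded rates are kept alongside for anyone preferring full
precision.

For each element the two LTRs are aligned globally (match +2, mismatch -1,
gap open -10, extend -0.5) and every column containing an indel is removed
(complete deletion) so only substitutions enter the p-distance. The age is

```
age = K / r_ltr          (default, convention "K_over_r")
age = K / (2 r_ltr)      (optional, convention "K_over_2r")
```

The wording "twice the synonymous rate used as the substitution rate
between LTRs" admits both readings. We default to `K / r_ltr` because the
zero-divergence upper bounds it implies (one substitution over an aligned
LTR length of ~720 or ~160 nt gives bounds of ~0.39 and ~1.76 MY)
correspond to plausible LTR lengths, whereas `K / (2 r_ltr)` would imply an
implausibly short ~80-nt LTR; both conventions are computed on request and
the output header names the one in force. For identical LTRs (K = 0) the
age is 0 and the finite upper bound `jc(1/L) / r_ltr` is reported, L being
the number of indel-free aligned columns.

`jc_distance()` rejects p >= 0.75 (the Jukes-Cantor saturation limit); a
saturated pair yields no age rather than a fabricated one.

## Read-mapping redundancy and the solo-LTR ratio

Reads are truncated to 75 nt so every read carries equal weight, then
mapped with a 15-mer-seeded ungapped mapper: a placement is accepted when
at least 90% of the read aligns at >= 90% identity, both orientations are
tried, each read is assigned to at most one reference, and ties between
references are resolved uniformly at random from the seeded stream
(`multiread` policy) or by reference order. Redundancy is reported as
mapped reads per kb of reference.

For the solo-LTR statistic the read set is mapped against two references
per element -- the 5' LTR and the inter-LTR region, with the 3' LTR
excluded. Exclusion is what makes the intact-family expectation equal 2:
each intact copy contributes two LTR copies (the 3'-LTR reads map onto the
5'-LTR reference) per internal region. With N intact copies and S solo
LTRs the expected ratio is (2N+S)/N, and families with a ratio above 2.5
are flagged as solo-LTR-rich -- a deliberately conservative threshold, half
a unit above the intact expectation. Reads spanning the LTR/internal
junction are counted for the partition holding the majority of their
aligned bases (exact ties go to the LTR): technically, an alignment
reaching a reference edge is accepted when at least half the read aligns
in-reference at the identity threshold. This reference-edge soft clipping
is what makes the expectation exactly (2N+S)/N at any read length; with a
hard 90% length-fraction cut at the edges the ratio would be biased low by
a factor of about (L - 30)/L for an LTR of length L with 75-nt reads. An
undefined ratio (no internal coverage) is reported as an `Inf`/`NaN`
sentinel, never dropped.

## RT phylogeny

Translated RT-domain hits of at least 80 aa are collected; pairwise global
alignments (BLOSUM62) give p-distances over gap-free columns, and
`ape::nj()` builds the neighbour-joining tree (negative branch-length
estimates are clamped to zero and flagged). Pairwise distances replace a
full multiple alignment: they are deterministic and sufficient as NJ input,
and the tests verify NJ exactness on additive matrices against an
exhaustive-topology least-squares oracle. Bootstrap supports come from
column resampling of a star alignment (all sequences projected onto the
positions of the longest one) -- an approximation of an MSA that is
adequate for support estimation but not a substitute for one; a
multiple-alignment plug-in point is left at `protein_distances()`. Families
are delimited by single linkage at distance <= 0.25 -- a numeric stand-in
for what is usually a visual, bootstrap-guided grouping; the cutoff is
configurable and family counts should not be over-interpreted.

## The simulator and what passing tests mean

`simulate_genome()` emulates the study conditions end to end: BAC-scale
contigs (25 x 50 kb by default), 20 families x 5 copies with copies of a
family placed on distinct contigs (mirroring BAC assemblies where a contig
rarely carries more than one or two elements), LTRs of 250-800 nt,
elements of a few kb, insertion ages uniform over 1-30 MY under the
3.6e-9 clock, TSD/PBS/PPT/TG...CA features on by default, 20x uniform
shotgun coverage with 100-nt reads at 0.5% substitution error, and 20
ortholog pairs of 120 codons at target Ks 0.077. Each family ORF is
back-translated with random synonymous codons plus ~8% point substitutions
so that families share domain content at the protein level without sharing
long identical DNA -- real families diverge this way, and without it any
two same-superfamily families would carry a byte-identical 2-kb ORF that
masquerades as an LTR pair.

LTR aging applies a per-branch Jukes-Cantor substitution probability
`(3/4)(1 - exp(-(4/3) b))` with branch length `b = r_ltr * age / 2`, so the
expected pairwise divergence matches the dating convention in force.
JC69 is the only mutation model; LTRs acquire no indels by default, and
nested insertions are not simulated (the detector does not resolve them
either). The simulator does not model tandem repeats, sequencing-quality
profiles, GC-biased gene conversion, or families sharing internal regions
-- so passing tests demonstrate correctness of the implemented chain under
its own model assumptions, not performance on real genomic complexity.

Problem sizes used by the test-suite and acceptance runs -- a 1.3-1.8 Mb
simulated genome, up to ~40,000 mapped reads per scenario, 500 dated LTR
pairs, NJ matrices up to 6 taxa against the exhaustive oracle -- were
chosen as the smallest sizes at which every statistical check retains a
comfortable margin (3-sigma bands well above the simulation noise floor).

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GFF3 output is 1-based
  inclusive. One conversion, at the file boundary.
* One run seed drives everything; each stochastic stage derives an
  independent stream (`derive_seed()`), so stages are order-independent
  and all text artifacts are byte-reproducible.
* TSD ties at equal length cannot arise (the match is anchored to the
  element); PPT ties prefer the window nearest the LTR, then the longer
  one; PBS ties prefer fewer mismatches, then the smaller offset, then the
  longer match.
* `genome_equivalents()` truncates (floors) to one decimal rather than
  rounding -- the conservative convention for library coverage.
* Standard errors use sd/sqrt(n), with SE = 0 reported for n = 1 groups.
* Empty inputs produce empty tables or header-only files, never errors;
  contigs under the length filter produce a warning and an empty result.

## Known limitations

* The bundled tRNA oligos and domain proteins are constructed stand-ins
  (files are labelled `synthetic`); supply curated FASTA files for real
  analyses.
* The mapper is ungapped; indel-rich read data would need the SAM
  ingestion path or an external aligner honouring the same thresholds.
* Per-element insertion ages at realistic LTR lengths carry an irreducible
  binomial sampling error of roughly 2.5-3 MY; means over sets of elements
  are accurate, single-element ages are not.
* Genome-fraction estimates (mapped/total reads) are only meaningful with
  whole-genome read sets, not with simulated or subsampled reads.
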