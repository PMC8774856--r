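---
title: "Methods: characterising a circular mitochondrial genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising a circular mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `mitoprofile`. The package implements the descriptive analyses that
accompany a newly assembled vertebrate mitogenome — composition and strand
skews, codon-usage bias, repeat and motif scanning, control-region
dissection, intraspecific variation statistics and distance-based
phylogenetics — together with a simulator that generates annotated
mitogenome-like data with known ground truth, so that every stage is
testable without sequence downloads.

## Coordinate and strand conventions

All coordinates are 1-based and inclusive, on the heavy (H) strand — the
convention of GenBank feature tables and of the printed gene tables this
package mirrors. Light-strand features are stored by their H-strand
coordinates plus a strand flag and are reverse-complemented on extraction,
so there is a single source of truth for positions. Wrap-around
(origin-spanning) features are not supported: the bundled mustelid layout
needs none, and a wrap-around feature must be split before ingestion.
Spacing between consecutive features is `next.start - prev.end - 1`;
negative values are overlaps, and for circular genomes the closure pair
(last feature, first feature) is included.

The bundled reference template (`lutreola_features()`) is the 39-feature
layout of a European mink mitogenome: 13 protein-coding genes (11,410 bp,
3,793 encoded amino acids, 31 bp of terminator nucleotides), 22 tRNAs,
2 rRNAs (2,530 bp), the light-strand replication origin and the 1,065-bp
control region. The per-gene tRNA sizes in the template sum to 1,512 bp,
which is what the printed coordinates imply.

## Composition and skews

AT-skew is `(A - T)/(A + T)` and GC-skew `(G - C)/(G + C)`. Percentages
are computed over the non-N total; N counts are carried separately and
excluded from every denominator. A skew whose denominator is zero is
reported as `NA`, never silently as 0. For report tables skews are rounded
to three decimals, half away from zero (the printed convention); raw
values are retained alongside. Partition profiles (all PCGs, all tRNAs,
all rRNAs, the non-coding remainder) count each genomic position once per
partition even when member features overlap, and always on the H strand.

CpG islands follow the observed/expected dinucleotide criterion:
a sliding window (default 100 bp, step 1) qualifies when G+C% exceeds 50
(strict) and `obs/exp = nCpG * window / (nC * nG)` is at least 0.6
(inclusive — resolving the two slightly different inequality statements in
common tool documentation; both thresholds are configurable). Qualifying
windows that overlap or abut are merged transitively, merged islands
shorter than 200 bp are discarded, and the reported GC% and obs/exp are
recomputed over the merged span. The implementation is checked against an
exhaustive window-enumeration oracle on kilobase-scale sequences.

Molecular weight sums average anhydrous nucleotide-monophosphate residue
masses (A 313.21, C 289.18, G 329.21, T 304.20 Da) per strand with a
-61.96 Da per-strand adjustment, doubled for the duplex. Web calculators
use slightly different mass dialects, so cross-tool agreement is expected
only at the percent level; the constants are documented in the source so
any deviation is explainable.

## Codon usage under the vertebrate mitochondrial code

Coding sequences are extracted on their coding strand and framed into
codons. A trailing length of 1 mod 3 is an incomplete single-T terminator,
2 mod 3 an incomplete TA terminator; both are completed with adenines to
TAA before any counting, mirroring mRNA polyadenylation — so completed
stops contribute to the TAA counts, as published codon-usage tables do.
An internal in-frame stop is an error naming the codon position; a
non-ATN start codon sets a flag rather than failing.

The genetic code is the vertebrate mitochondrial table (Biostrings table
2): stops {TAA, TAG, AGA, AGG}, Met {ATA, ATG}, Trp {TGA, TGG}, and no
one-fold families. Leu and Ser are treated as single six-fold families
(not split sub-families), which fixes the degeneracy-class structure at
12 two-fold, 6 four-fold and 2 six-fold families.

* **RSCU**: `k * count / family_total`; zero-count families give `NA`.
* **ENc** (Wright): per-family homozygosity
  `F = (n * sum(p^2) - 1)/(n - 1)` with families of count `n <= 1`
  excluded; `ENc = 12/mean(F2) + 6/mean(F4) + 2/mean(F6)`, clipped at 60.
  A class with no informative family has its mean imputed from the global
  mean of eligible families (Wright's fallback), flagged via an attribute.
  Under this code ENc spans exactly [20, 60].
* **CBI** (Bennetzen & Hall): `(N_opt - N_ran)/(N_tot - N_ran)` with
  `N_ran = sum(n_aa / k_aa)`. The optimal set defaults to the per-family
  argmax of the supplied usage with an alphabetical tie-break; a fixed set
  may be supplied.
* **GC3s**: under this code every sense codon's third position is
  synonymous, so GC3s is simply the G+C fraction of sense-codon third
  positions (stops excluded). The null curve of the ENc–GC3s plot is
  `ENc*(s) = 2 + s + 29/(s^2 + (1 - s)^2)`.

## Repeat, palindrome and motif scanners

All scanners treat N literally (N pairs only with N) and report 1-based
inclusive coordinates.

* **SSRs**: maximal perfect tandem runs, reported once with their
  smallest (primitive) period — `(AT)3`, never `(ATAT)1.5`. Unit lengths
  1–10 by default (1 covers homopolymer runs), at least 3 copies and 6 bp.
* **Approximate tandem arrays**: a seed-and-extend detector honouring the
  classic Tandem Repeats Finder weights (match 2, mismatch 7, minimum
  score 50, maximum period 500). Lag-p agreement seeds high-scoring
  segments under an X-drop; copies are compared positionally to the
  column-majority consensus; overlapping calls are resolved by score with
  ties to the smaller period, which collapses period harmonics. The full
  TRF wraparound indel alignment is not reimplemented — the `indel`
  weight is accepted for interface compatibility and documented as
  unused — so validation rests on planted-truth recovery (period, copy
  number within ±0.3, percent matches) rather than bit-agreement with any
  external tool. Because the detector reports the maximal-scoring
  segment, a planted array may extend by a fraction of a copy when
  flanking background happens to continue the period.
* **Inverted repeats / palindromes / hairpins** share one gapped-extension
  core: for every (position, spacer) the arm is extended to maximal
  length. SIRs use spacers 0–20 and arms 6–50; palindromes are the
  spacer-0 case (maximal per center by default; `count_all = TRUE` emits
  every nested even length, the convention of per-length palindrome
  censuses); hairpins restrict spacers to the loop range 3–20 with stems
  of at least 5 bp. Hits whose whole span lies inside a longer-armed hit's
  span are absorbed. Only exact arms are supported in this version.
  Each detector is property-tested against an independent brute-force
  enumeration on random sequences and is strand-symmetric (hit sets mirror
  under reverse complement).
* **Motifs**: ambiguity-coded patterns (N matches anything at zero cost)
  are matched on both strands via Biostrings, with circular scanning
  across the origin (a wrapped hit keeps its H-strand start; its end may
  exceed the sequence length, positions wrapping modulo the length).

## Control-region dissection

The control region is annotated from a versioned, user-editable motif
library (`cr_motif_library()`): ETAS1 with the embedded D-loop termination
motif `GCCCCAT`, TAS-A, the F/E/D/C/B boxes of the central conserved
domain, CSB1–3, the promoter cores and the `ATGN9CAT` palindromic motif.
Each element is located inside a search window (fractions of the CR span)
by semi-global minimum edit distance under a per-element cap; an element
whose best match exceeds its cap is reported as *missing*, never silently
placed. The minisatellite row is located with the tandem scanner and the
N-containing motifs with the exact motif scanner (all hits reported, since
the motif is its own reverse complement). Domain boundaries derive from
anchors: the central domain starts `cd_lead` (default 7) bp before the
F-box and ends `cd_tail` (default 89) bp after the B-box — the mustelid
layout — with ETAS upstream and CSB downstream to the CR ends.

Where published consensus sequences exist (`GCCCCAT`, `ATGN9CAT`,
`GCCGG`, the `GCACACGTAC` minisatellite unit) the library uses them; the
remaining rows are synthetic stand-in consensus sequences written for this
package and marked `synthetic` in the library's `source` column. The
bundled simulator plants exactly these sequences, so offline validation is
recovery of planted truth; real control regions require species-
appropriate consensus rows.

## Variation and diversity

Variant calling operates on a gap-aware multiple alignment with a
designated reference row. One call is made per polymorphic column
(multi-allelic columns count once, recording all alternates); contiguous
gap runs shared by the same rows merge into one indel event; a column
with both a substitution and a gap yields two calls. Substitutions are
transitions only if every ref-to-alt change is A<->G or C<->T. Positions
are reported on the gap-stripped reference; insertions take the position
of the preceding reference base. Coding effects translate reference and
alternate codons under the mitochondrial code (L-strand genes via
complemented alleles); indels inside genes are left unclassified
(frameshift annotation is out of scope).

Diversity statistics default to complete deletion (every gap/N column
excluded for all rows), the DnaSP-like convention: nucleotide diversity
pi is the mean pairwise difference per considered site, `k` the mean
absolute difference count, `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype
frequencies, and the conservation index `C` the monomorphic fraction of
considered sites. Haplotype partitions exclude indel columns by default,
so repeat copy-number variation does not split haplotypes; this is
configurable. Singleton and parsimony-informative sites are complementary
classes of variable sites (informative = at least two states each carried
by at least two rows). The haplotype network is the union of all minimum
spanning trees of the Hamming distance graph (an edge survives if its
endpoints are disconnected among strictly shorter edges) — a
minimum-spanning network, chosen over full median-joining because it
needs no median-vector inference yet reproduces the published topology
class for star-like intraspecific data. Windowed variability (default 50
bp windows, step 10) flags hypervariable-segment candidates where variant
incidence reaches 1 per 25 bp; the threshold is configuration, since
published HVS bounds are typically drawn by inspection.

## Distances, NJ and bootstrap

p-distances are mismatch proportions; TN93 uses the closed form with the
two transition classes and base frequencies estimated from the pooled
pair (not the whole alignment) — configurable, and cross-checked in the
tests against an independent implementation on two-row alignments, where
the two frequency conventions coincide. Pairwise deletion is the default
(each pair uses its own gap/N-free sites). A saturated pair (non-positive
correction logarithm) yields `NA` rather than a fabricated value.

Neighbour joining follows Saitou–Nei with the Studier–Keppler criterion;
ties in Q are broken by the lexicographically smallest representative-id
pair, making topologies deterministic. Negative branch estimates are
clamped to zero with the deficit moved to the sister branch
(Kuhner–Felsenstein), preserving path lengths; at the final trifurcation
negative estimates are simply clamped. On additive matrices NJ recovers
the generating topology and branch lengths exactly, which the property
suite verifies over random trees. The headline tree of the replication
study this package mirrors is a maximum-likelihood tree; distance-based
NJ on TN93 is used instead because the source analysis itself reports
that NJ yields the identical topology, and ML adds a large dependency
surface without adding testable signal.

Bootstrap supports resample alignment columns with replacement, rebuild
the tree per replicate, and report for each internal bipartition of the
point tree the percentage of replicates containing it; everything is
deterministic given the seed.

## The synthetic-data generator

`generate_genome()` draws an i.i.d. background at the published base
fractions (A 0.3282, C 0.2611, G 0.1383, T 0.2724 — A+T 60.06%), writes
the control region and origin stem-loop over it, gives every
protein-coding gene its template start codon and terminator, and removes
internal in-frame stops by single-base edits drawn from the same base
fractions (avoiding positions inside another gene's start/stop codons, so
overlapping genes converge). The control region is assembled at a fixed
internal layout with an RS3-style array of 22.1 unit copies by default,
planted microsatellites, and two `ATGN9CAT` copies; the array region is
CG-dense enough to double as a CpG-island positive control. Every plant
is recorded with exact coordinates in a truth table.

`simulate_haplotypes()` uses a star genealogy: each of `n` haplotypes
(default 6) mutates independently from the ancestor, keeping the expected
pairwise difference per ungapped site at `2 * mu` exactly (to first
order) and making truth enumeration trivial. Substitutions are per-site
Bernoulli(`mu`, default 0.002, capped at 0.01 to stay in the single-hit
regime); given a substitution the change is a transition with probability
`kappa/(kappa + 1)` (default kappa 10, i.e. a strongly
transition-dominated spectrum, as observed in conspecific mitogenome
panels). Indels (rate 1e-4 per site per lineage, geometric lengths,
mean 2) and per-haplotype minisatellite copy-number changes (SD 1 unit)
are emitted directly as alignment gaps, so no aligner is involved and the
output is already a valid multiple alignment.

What the simulator does *not* emulate: selection, rate heterogeneity
among sites, homoplasy (no multiple hits), heteroplasmy, and realistic
spatial clustering of variation beyond the VNTR. Green tests on
simulated data therefore demonstrate the correctness of the estimators
and scanners under their stated models, not robustness to every property
of real data — in particular, alignment errors and reference-assembly
artefacts are upstream of this package's scope.

## Problem sizes used in the checks

The test-suite and acceptance script run at desk scale: full-length
(16.5 kb) synthetic genomes for end-to-end stages, 150–500 bp random
sequences across 20 seeds for the scanner-versus-oracle equivalences, 100
replicates of a 2-kb, 6-haplotype star simulation for the `E[pi] = 2 mu`
Monte-Carlo check (within three standard errors), and bootstrap runs of
100 replicates on small alignments for the determinism and clean-signal
contracts. These sizes were chosen so the whole suite exercises every
code path in a few minutes on a laptop while keeping Monte-Carlo
standard errors small relative to the tolerances tested.

## Command-line use

The package's interface is its R functions; a thin wrapper,
`inst/scripts/mitoprofile.R`, exposes the one-call pipeline
(`run_characterization()`) to shell users, and YAML configuration files
(see `read_run_config()`) override the documented defaults, every one of
which is a published scan parameter. Accession-based replication of the
source study requires network access; `scripts/fetch_accessions.R`
fetches and aligns the deposited sequences, after which the
accession-based acceptance checks run against them.

## Known limitations

* Scanners support exact arms/units only (`mismatches = 0` for inverted
  repeats and hairpins); the tandem detector approximates TRF without the
  wraparound indel alignment.
* The control-region library ships synthetic stand-in consensus rows for
  elements whose published consensus is not freely reproducible; real
  annotations need user-supplied rows.
* Indel coding effects (frameshifts) are not classified.
* TN93 is undefined for saturated pairs and reported as `NA`; the NJ
  stage requires a complete matrix.
* The thermodynamic stability of hairpins/secondary structures is out of
  scope; hairpin calls are purely sequence-complementarity based.
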