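---
title: "Methods: quantitative CpG methylation from long-read amplicon bisulfite sequencing"
author: "smrtbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative CpG methylation from long-read amplicon bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Targeted bisulfite sequencing estimates, for each CpG dinucleotide in a
region of interest, the fraction of input molecules that carried a methyl
group at that cytosine. Bisulfite treatment deaminates unmethylated cytosine
to uracil (read as T after PCR) while 5-methylcytosine is protected, so
methylation state becomes a sequence difference. Long (CCS-level) amplicon
reads make it possible to interrogate regions up to ~1.5 kb — enough to span
most CpG islands in one amplicon — and to multiplex many samples with
barcoded universal primers.

`smrtbs` implements the analysis side of such an experiment: barcode
demultiplexing, bisulfite-aware alignment, per-read quality filters,
depth-gated per-CpG quantitation, reproducibility statistics, the equimolar
pooling calculation for the bench, and a simulator that generates barcoded
bisulfite reads with known ground truth so every stage can be validated
without sequencing data.

## Coordinates and site maps

Internally all coordinates are 0-based, half-open; every exported table is
1-based and says so in its column names. For each amplicon the package
precomputes three maps from the reference sequence:

* `cpg_sites` — forward-strand positions of the C of each CpG. CpG is
  palindromic, so this one coordinate indexes the biological site on both
  strands; bottom-strand evidence (the paired G at position p+1) is reported
  back under the same key.
* `noncpg_c_top` / `noncpg_c_bottom` — cytosines outside CpG context on
  each strand. These are expected to be unmethylated in most mammalian
  contexts and therefore measure per-read bisulfite conversion.

`N` bases are tolerated in references; any position whose dinucleotide
context involves an `N` is excluded from the maps. A terminal C (no
following base) counts as non-CpG, as does a leading G on the bottom
strand, so the CpG/non-CpG partition covers every cytosine of an N-free
sequence.

## Demultiplexing

Barcode matching uses Levenshtein edit distance with a default budget of 2
edits per 18-bp barcode — "mismatches" here include insertions and
deletions, which matters for a platform whose residual errors are mostly
indels. The search window is the first `barcode_length + max_edits` bases of
the read in each orientation, and the distance is minimised over candidate
barcode end points so an indel inside the barcode does not shift the frame.
Two design rules are deliberately conservative:

* a read equidistant from two samples' barcodes is left unassigned —
  cross-contaminating a sample is worse than losing a read;
* when the 3' (reverse) barcode is found within the same budget but points
  to a different sample than the 5' barcode, the read is binned as
  `barcode_conflict` rather than trusted.

Trimming removes barcode and universal primer at their best sub-alignment
at both ends; if a primer is not locatable within its own edit budget
(default 3), only the barcode is trimmed and the read is flagged. The
minimum-length filter keeps reads strictly longer than 50 bp by default
(`inclusive = TRUE` exposes ≥).

## Bisulfite-aware alignment

After conversion the two strands of a template are no longer complementary,
so each read is evaluated against four candidates per amplicon: read and
reverse complement, against the C→T-converted top strand and the
G→A-converted bottom strand, with the read collapsed into the same
three-letter space (C/T or G/A merged). Collapsing makes conversion
alignment-neutral; methylation state is read back afterwards from the
original, uncollapsed bases. This is the standard three-letter strategy of
bisulfite aligners, implemented here at amplicon scale with
`Biostrings::pairwiseAlignment`.

Alignment is semi-global — the read is aligned end-to-end, reference
flanks are free — with affine gaps. Defaults (exposed in `align_params()`):
match +2, mismatch −3, gap open 5, gap extend 2 (a gap of length L costs
`5 + 2L`), minimum identity 0.7 in converted space. These are this
package's own choices for CCS-accuracy reads; nothing downstream is
sensitive to them at CCS error rates. Scoring is done for all candidates in
a fast score-only pass; only each read's winning candidate is realigned
with traceback. Ties across amplicons discard the read as ambiguous; ties
within an amplicon break deterministically (top before bottom, forward
before reverse-complement).

Call extraction walks the gapped alignment once: a read base over a
reference cytosine yields METH/UNMETH (CpG) or RETAINED/CONVERTED
(non-CpG); a deletion over a cytosine or an unexpected base yields AMBIG; a
position outside the aligned span is UNCOVERED; read insertions contribute
nothing because they have no reference coordinate.

## Read filters

Two per-read filters run in order, and their report conserves reads exactly
(`n_input = n_low_conversion + n_clonal_removed + n_pass`):

1. **Conversion rate** — `CONVERTED / (CONVERTED + RETAINED)` over covered,
   unambiguous non-CpG cytosines. Reads below 0.95 fail (boundary
   inclusive: exactly 0.95 passes). A read with no informative non-CpG
   cytosine cannot be verified and fails by default (configurable).
2. **Clonal artifacts** — reads whose CpG *and* non-CpG call vectors are
   identical across the whole amplicon site map (including UNCOVERED
   positions, i.e. identical spans) on the same strand are grouped; one
   representative per group survives (first after a stable sort by read id,
   so results are order-invariant). `drop_all_clones` removes whole groups
   instead. The filter is defined on patterns, not provenance: two
   independent molecules that happen to share the full pattern are
   indistinguishable from PCR siblings and are collapsed too. With ~100
   stochastically converted positions per read that coincidence is
   negligible; on short amplicons with very high conversion efficiency it
   is not, which is worth remembering when interpreting clonal counts from
   short designs.

Conversion filtering is unbiased for methylation because conversion
failures at CpG and non-CpG sites are independent given a molecule's
efficiency: removing reads with many retained non-CpG cytosines does not
condition on their CpG states.

## Quantitation and statistics

Per site, `level = n_meth / (n_meth + n_unmeth)`; AMBIG calls leave both
numerator and denominator. Sites with informative depth below 10X are
dropped from exported profiles (the depth gate). Replicate statistics
restrict to sites past the gate in *all* replicates: pairwise Pearson r
over site levels, per-site standard deviation with the n−1 denominator,
and the median SD. A replicate with zero variance across common sites has
no defined correlation and is reported as `NA`, never silently as 0 or 1 —
this matters for amplicons that are fully (un)methylated, where
"correlation" would only measure noise. For overall reproducibility the
package computes both pairings: amplicon-level r, and r over the pooled
common sites of all amplicons (informative when truth spans the 0–1
range).

Cross-platform comparison (`compare_platforms`) intersects two
site-to-level maps, reports Pearson r and the signed per-site differences;
a persistent downward shift of intermediate levels is the signature of PCR
bias towards unmethylated templates.

`pooling_volumes` implements the equimolar pooling formula
`V_i = M·L_i / (n·C_i·ΣL)`. Mass is proportional to molecules × length, so
allocating mass ∝ length equalises molecule counts: `V_i·C_i/L_i` is
constant across amplicons and total dispensed mass is exactly `M` — both
identities hold to machine precision and are tested on random
specifications.

`island_coverage` reports the fraction of CpG-island intervals whose
length fits a single amplicon of at most 1500 bp (inclusive boundary,
since ~1.5 kb amplicons are achievable). Applied to a genome-wide island
track this estimates the fraction of islands the method can interrogate
with one amplicon; the package validates the computation on constructed
BED input and does not ship a genome track.

## The simulator

The simulator generates what the wet lab would deliver: barcoded,
bisulfite-converted, CCS-level amplicon reads, plus a truth table. Per
molecule: methylation states are independent Bernoulli draws at each
site's true level; unmethylated CpG and all non-CpG cytosines convert with
probability `conversion_efficiency` (methylated CpGs never convert);
strand is uniform. Reads sample *distinct* molecules (weighted by
`pcr_bias_weight^(#unmethylated CpGs)`, uniform at the default w = 1) from
a pool 10× the read count, so that the explicit `clonal_fraction`
mechanism — re-emitting a previously emitted molecule's exact converted
sequence — is the only source of clones and the truth table stays clean.
Barcodes and universal primers are attached unconverted (they enter after
conversion in a two-step PCR design), half the reads are flipped to the
opposite orientation, and substitution/indel errors are injected
per base. The same seed reproduces every output file byte for byte.

Defaults encode the emulated study conditions: conversion efficiency 0.97,
clonal fraction 0.003, substitution error 0.005, indel rate 0.001,
100 reads per sample×amplicon, w = 1. The default three-amplicon design
(`island_profiles`) emulates CpG islands with low (all sites 0),
intermediate (imprinted-like; site levels cycling 0, 0.25, 0.5, 0.75, 1,
mean 0.5), and high (all sites 1) methylation. The intermediate island is
deliberately heterogeneous: replicate correlation over a flat profile
would measure only noise, whereas real intermediately methylated islands
carry site-to-site structure.

An `exact = TRUE` mode replaces sampling with exhaustive enumeration
(molecule j of d has site s methylated iff `j ≤ round(level_s·d)`,
complete conversion, alternating strands), so a full pipeline pass over
all templates must recover every level exactly — note the clone filter
must be off for this property, because enumeration re-emits identical
patterns by construction.

What the simulator does not model: chimeric PCR products, bisulfite
degradation and fragment-length effects, quality-score structure
(qualities are constant; the pipeline does not use them), co-methylation
(haplotype correlation between neighbouring sites), and raw
polymerase-read/ZMW behaviour upstream of CCS. Passing tests therefore
demonstrate correctness of the analysis under these idealised error
processes, not performance on any particular instrument run.

## Verification strategy and numerical choices

* Alignment scores are checked for exact equality against an independent,
  hand-written semi-global Gotoh dynamic program on random instances up to
  300 bp; demultiplexing decisions against a full edit-distance DP on
  constructed prefixes.
* Parameter recovery is tested at triplicate 100X on 700 bp amplicons with
  24 CpGs. The per-site truth baseline is the analytic expectation of the
  *observed* level under the simulator's own noise model
  (conversion failure moves unmethylated sites up by ~(1−eff); uniform
  substitution error mixes the two informative bases), with a 3-SE
  binomial band on replicate-pooled estimates — at levels 0 and 1 the raw
  truth has zero binomial SE, so the noise-model expectation is the only
  baseline under which a 3-SE test is meaningful.
* Clonal-filter removals are compared exactly against an O(n²) all-pairs
  oracle, and against truth-derived template identity as a lower bound.
* The depth–variance law (per-site SD ≈ `sqrt(0.25/depth)` at level 0.5)
  is verified across depths 20–200X with 50 replicate simulations per
  depth, within 20%: sampling depth, not chemistry, dominates
  reproducibility of intermediate methylation.
* Problem sizes throughout (3 amplicons × 3 replicates × 100X; 150–700 bp
  test amplicons; 50-replicate variance studies) are the package's chosen
  verification scale: large enough for 3-SE statistics to discriminate,
  small enough to run routinely.

Degenerate inputs are reported, not guessed: empty BED → explicit
`"empty"` status; zero-variance correlation → `NA` with a counted reason;
unverifiable conversion → flagged and failed by default; malformed BED
intervals are rejected with their line number.

## Known limitations

* Alignment is to amplicon references only; there is no genome-scale
  index, no variant calling, and — as for all bisulfite methods —
  no discrimination of 5-hydroxymethylcytosine from 5-methylcytosine.
* The clonal filter's identical-pattern definition over-counts on short,
  nearly fully converted amplicons (see above) and cannot see clones whose
  copies acquired sequencing errors at cytosine positions.
* Methylation levels from amplicon bisulfite PCR can be biased towards
  unmethylated templates; the simulator reproduces the direction of this
  bias (`pcr_bias_weight > 1` shifts intermediate levels down by
  `p/(p + w(1−p))` in the single-site case, fixed points 0 and 1
  unaffected) but the package does not attempt calibration — standard
  curves from methylation controls are the usual remedy.
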