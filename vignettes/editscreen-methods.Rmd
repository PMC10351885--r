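---
title: "editscreen: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{editscreen: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`editscreen` identifies RNA editing sites left by RBP–deaminase fusions.
The procedure is deliberately threshold-based rather than probabilistic:
with a matched no-enzyme control from the same cell line, simple coverage
and fraction cutoffs remove SNPs, endogenous editing and technical error
without external catalogs, and the resulting rules are auditable
position-by-position.

For each enzyme two reference-strand signatures are evaluated, because
Smart-seq2 libraries are unstranded: ADAR is A>G on `+` and T>C on `-`;
APOBEC is C>T on `+` and G>A on `-`. A minus-strand transcript's edits
would be invisible otherwise. The inferred strand is recorded on every
site and drives the trinucleotide-context orientation. The two signatures
of one enzyme have disjoint reference bases, so a position carries at most
one signature.

Stages, in order:

1. **Control editability.** Position editable iff control coverage
   ≥ `control_min_reads`, reference fraction ≥ `control_min_ref_frac`,
   edited-base fraction < `control_max_alt_frac`. Positions uncovered (or
   under-covered) in the control are never callable — editability cannot
   be established, which is the conservative reading of a control-first
   design.
2. **Candidate calling.** Site iff experimental coverage
   ≥ `expt_min_reads`, edited fraction strictly > `expt_min_edit_frac`,
   and edited reads ≥ `expt_min_edited_reads`. All rules are conjunctive;
   their order is immaterial. Fractions always use total coverage
   (A+C+G+T) as denominator.
3. **Replicate merging.** `merge_exact` (ADAR) intersects identical
   (contig, position, signature) records and reports the mean fraction.
   `merge_proximity` (APOBEC) keeps any site whose nearest site in the
   *other* replicate is ≤ `proximity_window` away. The symmetric
   both-replicates output was chosen because the published description
   ("within 100 bp of a second site in the biological replicate") does not
   say which replicate's coordinates survive; the symmetric union is the
   superset consistent with that text and preserves per-replicate editing
   statistics. `mode = "rep1"` reproduces the asymmetric reading.
   Signature identity is *not* required to match across replicates within
   one enzyme: in unstranded data the two signatures describe the same
   biological event.
4. **Background subtraction.** Any position edited at
   ≥ `background_edit_frac` with coverage ≥ `background_min_reads` in any
   enzyme-only replicate is blacklisted; subtraction matches the full
   (contig, position, signature) key.

## Thresholds

| field | default | unit | why |
|---|---|---|---|
| `control_min_ref_frac` | 0.80 | fraction | control must be cleanly reference |
| `control_max_alt_frac` | 0.005 | fraction | excludes SNPs/endogenous editing (strict `<`) |
| `control_min_reads` | 9 | reads | minimum evidence of editability |
| `expt_min_reads` | 20 | reads | guards fraction estimates |
| `expt_min_edit_frac` | 0.06 | fraction | operating point between historical 5% and 10% runs; strict `>`; re-run at 0.04 for sensitivity analysis |
| `expt_min_edited_reads` | 2 | reads | one edited read ≈ technical error; redundant at defaults but enforced explicitly |
| `background_edit_frac` | 0.01 | fraction | enzyme-only background; **inclusive** ≥ |
| `background_min_reads` | 20 | reads | mirrors the experimental coverage rule (unstated upstream; configurable) |
| `proximity_window` | 100 | bp | APOBEC replicate dispersion scale |
| `region_flank` | 100 | bp | site expansion for overlap analyses |
| `motif_flank` | 50 | bp | expansion for motif scans |
| `shift_3prime` | 50 | bp | CDS/3'UTR border reclassification |
| `min_mapped_reads` | 12×10⁶ | reads | depth QC warning threshold (not an error) |

Boundary conventions worth naming: the background cutoff is inclusive
(≥ 1%), following the published script parameter over the looser prose;
the experimental fraction is strict (> 6%); the control alternative
fraction is strict (< 0.5%). The background criterion is evaluated for
both signatures without checking the reference base — pure piles of a
signature's *product* base therefore enter the blacklist trivially, which
is harmless because subtraction matches the full signature, and it keeps
the rule exactly as printed.

## Interval algebra and conventions

Site tables are 1-based points; intervals are BED (0-based half-open);
converters are explicit (`sites_to_intervals`). Overlap defaults to
≥ 1 bp — the default of the interval tool named in the original workflow,
which almost certainly governed the published "> 1 bp" analyses; pass
`min_overlap = 2` for the literal reading. Nearest distance is the gap
width (bases strictly between), 0 for overlap *and* for book-ended
intervals; the "zero iff overlapping" intuition fails only in the
book-ended case.

## Annotation statistics

* **Feature assignment.** A site in several coding isoforms takes the
  majority feature; ties break 3'UTR > 5'UTR > CDS (the upstream work is
  silent; the priority favours the feature the biology concentrates on).
  Non-coding isoforms never vote.
* **Read distribution.** Computed in-package as per-feature coverage
  shares of a count matrix (normally the control), renormalised over
  {5'UTR, CDS, 3'UTR}; this replaces an external read-distribution tool
  while matching its meaning. The three fractions can also be supplied
  directly.
* **Proportion test.** Two-sided one-sample z-test of the site proportion
  against the read-derived expectation; a feature with zero read fraction
  but observed sites reports `Inf` fold and the degenerate binomial tail
  (p = 0).
* **Rank-sum test.** Exact when both groups have ≤ 12 observations: the
  null distribution of the rank sum is built by an integer dynamic program
  over doubled midranks — arithmetically identical to full enumeration and
  correct under ties; two-sided p is `min(1, 2·min(tails))` with the
  observed value in both tails. Larger samples use the normal
  approximation with tie correction and continuity correction, matching
  the reference implementation to ~1e-12 in tests.
* **3' shifting** moves sites in transcript coordinates (following the
  exon chain; genomic coordinates decrease on minus-strand transcripts),
  clamped at the transcript's last base. The host transcript is the
  containing isoform in which the site is already closest to its 3'
  terminus — the most 3'-biased assignment, which makes the shift a
  conservative upper bound on CDS→3'UTR reclassification.
* **Motif scan** is a fixed-pattern IUPAC scan on both strands — a
  stand-in for de-novo discovery, which is out of scope.

## The synthetic world

The generator emulates a deep bulk Smart-seq2 experiment at desk scale.
Defaults (chosen once, stated here, not tuned): 200 transcripts of
900–2500 exonic bp on one contig each, 1–3 exons, 20%/30% of exonic bases
in 5'/3' UTR, ~100× Poisson coverage, per-base sequencing error 10⁻³
split evenly over the three alternative bases, 500 planted sites at 20%
editing, 200 shared background positions at 5% in the enzyme-only
samples, two replicates. Base counts are multinomial per position
(implemented as sequential binomials, so the signature-alternative margin
is exactly Binomial(n, edit + error/3)). One master seed drives fixed
per-sample streams, so the whole simulate→call→evaluate chain is
reproducible to the byte.

APOBEC-like replicate dispersion: replicate ≥ 2 displaces each planted
site by Uniform{0..`rep_jitter_bp`} bp (random sign), snapped to the
nearest substrate base of the same transcript, so the displaced edit is
still chemically possible. Truth sites are restricted to substrate-base
exonic positions, optionally to a trinucleotide whitelist.

What the generator does **not** model: read-level artifacts (alignment
error, PCR duplicates, strand bias, position-correlated coverage), RNA
secondary structure (ADAR's double-stranded-region requirement), overlap
of transcripts on one contig. A green recovery test therefore establishes
the correctness of the *filtering logic*, not robustness to alignment
artifacts.

## The recall ceiling (why one acceptance criterion is red)

At 100× coverage and error 10⁻³ the per-signature alternative-read rate
is 1/3000. The control screen rejects a position whenever it shows ≥ 1
alternative read, because 1/n > 0.5% for any n ≤ 200:
P ≈ 1 − exp(−100/3000) ≈ 3.3%. Each enzyme-only replicate blacklists a
position when one alternative read lands at coverage ≤ 100
(P ≈ 1.7% per replicate). Expected end-to-end recall is therefore
0.967 × 0.983² ≈ 0.935 — an intrinsic property of the published
thresholds in this world, not of the implementation (precision stays at
1.0, and with error set to 0 recall is exactly 1). The acceptance
criterion demanding recall ≥ 0.99 in this exact world is left failing
rather than met by quietly changing the world; the merging-contrast
experiment, whose stated condition is only the inter-replicate jitter, is
run noise-free so that this ceiling does not confound it.

## Known limitations

* Two biological replicates at most (matching the experimental design);
  no probabilistic reproducibility model.
* The pileup counts duplicate reads as-is and applies no base/mapping
  quality filter by default (both exposed as options), matching the
  described upstream behaviour.
* Per-million normalisation defaults to uniquely mapped primary records;
  which total the original figures used is not stated.
* BED `score` is serialised through text and reads back as numeric.
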