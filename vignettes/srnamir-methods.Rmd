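---
title: "Methods: small-RNA miRNA discovery and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA discovery and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`srnamir` implements the computational arm of a small-RNA sequencing study
of miRNA biogenesis in *Chlamydomonas reinhardtii*, where libraries from a
wild-type strain (CC-5325) and a Dicer-like (*dcl1*) insertional knockout,
three biological replicates each, are compared to find miRNAs whose
production depends on the disrupted protein. The pipeline covers: raw-read
cleaning into counted clean tags, tag annotation against contaminant
non-coding RNA and known-miRNA references and the genome, novel miRNA
discovery from hairpin (stem-loop) folding with miRNA/miRNA\* duplex
evaluation, stem-loop re-classification of previously reported miRNAs, and
TPM-based differential expression with significance tiers. A synthetic-data
generator plants hairpin loci with known ground truth so the whole chain is
testable without the original sequencing archive.

# Read cleaning

A raw read is rejected, in this fixed order, when

1. its mean Phred quality is at or below 20 ("Q value <= 20" is read as the
   mean score of the read; the per-base alternative is a stricter reading
   and the threshold is exposed in `clean_params()`),
2. it contains an unknown nucleotide `N`,
3. no 3' adapter is found — detection is an exact match of the adapter's
   first 8 bases at or after read position 18, a deterministic prefix-seed
   rule; on a match the adapter and everything after it is trimmed,
4. the trimmed insert still contains the 5' adapter (exact match of the
   adapter's last 8 bases — the bases a 5'-ligation junction would leave;
   bases after the 3' adapter are filler and are not searched),
5. the insert is shorter than 18 nt,
6. the insert is polyA — at least 80% A, or an A-run of 10 or more (both
   clauses configurable; "contains polyA" has no standard definition),
7. the insert is longer than 30 nt, mirroring the 18-30 nt gel
   size-selection window of the library protocol.

Survivors collapse into **clean tags** — unique insert sequences with one
count per library, ordered by descending total count then sequence, so the
table is invariant to read order. Per library, rejection tallies plus
survivors always equal the input read count; this conservation identity is
asserted by the tests.

A consequence of the position-18 seed rule is that an insert of 17 nt is
the only length that can be *observed* as "shorter than 18": anything
shorter places the adapter before position 18 and is rejected as
missing-adapter instead. The defective-read generator plants 17-nt inserts
for exactly this reason.

# Annotation cascade

Each tag receives exactly one tier, in the order the original analysis
applies them: `contaminant` (substring match, both orientations, 0
mismatches by default, against the rRNA/snoRNA/snRNA/tRNA reference),
`known_miRNA` (same search against the known-mature reference, up to 2
substitutions by default — the tolerance the study used is not recoverable,
so it is configurable), `genome_mapped` (all exact full-length genomic
occurrences on both strands), else `unmapped`. A sequence present both in a
contaminant and in the genome is a contaminant — cascade dominance.

Genomic hits are classified by the highest-priority feature kind they
overlap (strand-agnostic, one shared base suffices): exon > 3'UTR >
intron, with `intergenic` for no overlap. Introns are derived from the gaps
between consecutive exons of one transcript when the annotation does not
state them.

Tags whose hits lie in exon or 3'UTR sequence are treated as likely mRNA
degradation fragments: they are flagged and never seed novel-miRNA
candidates. This follows the original pipeline's order (degradation removal
before novel prediction) and its outcome (novel miRNAs reported only from
intron and intergenic loci; exon-hosted miRNAs enter through the
known-miRNA reference). Without this guard, maximum-pairing folds admit a
steady trickle of exonic fragments as false loci. Tags with more than 10
genomic hits are treated as repeats and likewise excluded from discovery,
while remaining quantifiable as known miRNAs.

# Hairpin folding and duplex evaluation

The folding engine is deliberate, self-contained base-pair maximization
(Nussinov-style dynamic programming) over A·U, G·C and the G·U wobble,
with hairpin loops of at least 3 unpaired bases. Traceback is
deterministic: a pairing of the 5'-most open position is preferred over
leaving it unpaired, and the smallest optimal partner index wins. The pair
count, also expressed per base, stands in for free energy; the engine is
verified against exhaustive enumeration of all non-crossing structures for
sequences up to 14 nt. A thermodynamic nearest-neighbor model would be more
selective but is not oracle-verifiable in closed form; the score threshold
compensates (below).

For every candidate tag hit, two windows are folded, placing the tag on the
5' arm and on the 3' arm (default flank 180 nt, matching reported precursor
spans of roughly 90-370 nt). Given a fold and the mature's offsets, the
duplex is summarized by:

* **star segment** — the positions pairing with the mature, extended by
  2 nt at its 3' end: the Dicer/DCL cut signature of 2-nt 3' overhangs on
  both strands;
* **mismatches** — mature bases left unpaired (at most 4 by default);
* **bulges** — asymmetric stretches, counted whenever the unpaired star
  bases between two consecutive mature pairs exceed the unpaired mature
  bases in the same gap (at most 2); symmetric internal loops are already
  captured by the mismatch count;
* **pairing fraction** — paired mature bases over mature length (at least
  0.6);
* **fold score per base** (at least 0.25 pairs/nt over the window);
* **clean cut** — both mature ends paired, i.e. the canonical overhang
  geometry is available. This is a ranking feature, not a hard filter,
  because real DCL products (and the simulator) have ragged ends.

A mature that pairs with itself or on both sides of its own position spans
the terminal loop and is rejected outright. Candidates also need a total
tag count of at least 3 and a mature length of 18-24 nt. Overlapping
passing windows collapse to one locus: highest count, then clean-cut
duplexes, then fold score. Novel calls are named `novel-miRNN` in rank
order of total count.

# Re-classification of reported miRNAs

miRBase-style entries whose recorded precursor no longer matches the
genome are re-examined: if the recorded precursor maps exactly, the record
stands (no group). Otherwise the mature is mapped and precursor
re-prediction runs at every hit. No passing precursor puts the entry in
group I (non-miRNA); a passing precursor whose mature is completely
complementary to its star — no mismatches, no bulges, and strictly
Watson-Crick by default (whether the original "completely complementary"
tolerated G·U is unknowable, so wobble-perfect duplexes fall to group II
under the default) — is group III, siRNA-like; anything else is group II,
a miRNA candidate with a re-predicted interval and location. The three
groups are mutually exclusive and exhaustive by rule order.

# Quantification and differential expression

TPM follows the printed formula: count / total clean tags x 10^6, with the
denominator being *all* clean tags of the library, not only miRNA-mapped
ones. A miRNA's count sums the tags inside its mature interval extended by
2 nt on either side (isomiR window, configurable 0-2), capturing ragged-end
variants; known miRNAs additionally count their reference-matched tags,
which already absorbs isomiRs through the 2-substitution match.

Fold change is mutant over control mean TPM; a pseudocount of 0.01 TPM
substitutes for an exactly zero mean, and a record with both means zero is
flagged undefined. Significance uses Welch's two-sided t on
log2(TPM + 1) — the study never names its test, and an honest two-group
comparison at n = 3 is what the design supports. The 1-TPM transform
pseudocount keeps zero-count replicates from dominating the variance (with
0.01 a single zero produces a -6.6 outlier on the log2 scale and destroys
power exactly where knockouts are strongest); an exhaustive permutation
test serves as the cross-check in the test-suite. Degenerate inputs are
exact: identical groups give p = 1, zero variance with different means
gives p = 0.

Down-regulation requires log2(fc) <= -log2(1.5) with p < 0.05 (up is the
mirror image); significantly down records split into the high tier
(log2 fc <= -1, boundary inclusive — the published footnote writes both
tiers with a closed bound at -1, and high is given precedence) and the
medium tier (-1 < log2 fc <= -log2 1.5). No multiple-testing correction is
applied, matching the original analysis. Applying these thresholds to the
22 published log2(fc) values reproduces the published 14 high / 8 medium
split, and recomputing log2(fc) from the printed group means matches the
printed values within +/-0.01 wherever the means are at least 1 TPM
(coarser rows cannot reproduce their own quotient at that precision).

The stem-loop RT-qPCR arm of the study is covered by `ddct()`:
2^-((Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control).

# The synthetic study

`sim_config()` fixes the simulated conditions; the defaults are the
package's standing study design, not tuning knobs:

* **Design**: 2 groups x 3 replicates, 200,000 reads per library, read
  length 50, one 100-kb chromosome, 20 hairpin loci, 8 gene models.
* **Precursors**: pad(5) + arm(40) + loop(12) + reverse-complemented
  arm + pad(5), 0-3 planted stem mismatches placed under the mature, mature
  20-23 nt with the length assignment re-drawn until 21 nt carries the
  plurality of expected read mass (so the count-weighted length mode is
  21 nt whichever locus dominates), 5'-U probability 0.7 — the length mode
  and 5'-U bias the study describes. Star reads at 1:10 to mature; 10% of mature reads
  carry +/-1-nt ragged ends to exercise isomiR counting and the
  overhang-as-ranking decision.
* **Locations**: half intergenic, 30% intron, 10% exon, 10% 3'UTR, so
  intergenic is the plurality as observed; exon/UTR loci are emitted into
  the known-miRNA reference (see the degradation guard above).
* **Abundance**: locus weights log-uniform on 10^[-2.5, 1.5]. This spans
  baseline TPM from tens to a few hundred thousand — the span of the
  published quantifications — while capping how much of a library a single
  locus can hold: because the simulator draws *absolute* negative-binomial
  counts (mean = baseline x knockout effect, dispersion 0.1), knocked-out
  mass shrinks the mutant library total and compresses every measured fold
  change through the TPM denominator. The effect is real compositional
  behavior (the study itself sees up-regulated miRNAs in the knockout) and
  is kept, but bounded.
* **Knockout effects**: {0.04, 0.07, 0.09, 0.12, 0.15, 0.20, 0.25, 0.25}
  on eight loci, 1.0 elsewhere — the strongly down-regulated regime
  (log2 fc about -4.6 to -2) in which a knockout phenotype is unambiguous
  at n = 3. Milder effects are configurable but sit at the detection
  boundary of a three-replicate design by construction.
* **Noise floor**: 50% contaminant reads (cut from random non-genomic
  rRNA/tRNA/sno/snRNA stand-ins), 15% exonic degradation fragments, 3%
  defective reads split evenly over the six cleaning-filter classes,
  leaving about a third of each library as miRNA and star reads. Real
  sRNA libraries are dominated by ncRNA fragments, and the published
  quantifications imply the same minority miRNA share (the printed control
  TPMs of the dominant miRNAs sum to well under 20% of a million); this
  matters statistically, because the TPM denominator is total clean tags —
  were miRNA mass the majority, knocking out a dominant locus would
  compress every other fold change through the denominator and break the
  assumption the TPM comparison rests on.
  Adapter seeds (3' prefix, 5' suffix, both orientations) are masked out of
  the genome background and contaminant references so adapter detection is
  exact by construction.

What the generator does **not** emulate: sequencing errors beyond quality
strings, PCR duplicates, fixed sequencing depth (libraries are resampled
in reality; here totals float with the biology), genome repeats, and a
realistic transcriptome-wide degradation spectrum. Passing the recovery
tests therefore shows the machinery is correct under the stated model, not
that the thresholds are optimal for any real library.

# Numerical choices and degenerate inputs

Coordinates are 1-based inclusive throughout, as in the published tables;
`-`-strand windows return reverse-complemented sequence. RNA input is
normalized to the DNA alphabet (U -> T) at every boundary. FASTQ is 4-line
Phred+33 only. Folding ties break toward the 5'-most closing pairing;
collapse ties break by count, cut geometry, score, then sequence, so all
outputs are deterministic and a rerun of the same configuration is
byte-identical. Empty reads reject as "short"; an empty tag set yields an
empty (but well-formed) tag table; summaries of zero records warn and
return zero counts.

# Problem sizes used in validation

The validation suite runs the full default simulation (20 loci, 200k reads
x 6 libraries) once, a 200-locus null count simulation for type-I error,
and 500-sequence fold-enumeration equivalence at length <= 14; unit tests
use 6-locus, 2,500-3,000-read miniatures of the same design. These sizes
were chosen to exercise every code path at comfortable margins.

# Known limitations

* Base-pair maximization over-pairs relative to thermodynamics; the duplex
  metrics and the degradation guard carry the discriminative burden that
  an energy model would otherwise share.
* With three replicates, loci whose true fold change sits near 1.5x, or
  whose measured fold change is compressed by large compositional shifts,
  are detected with limited power — a property of the design, visible in
  the published medium tier as much as here.
* Known miRNAs without a mappable mature sequence are quantified purely by
  reference matching and carry no location class.
* The re-classification of wobble-perfect duplexes (group II vs III)
  follows a convention; flip `wc_only_for_sirna` to adopt the other
  reading.
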