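---
title: "Locating a bacteriocin target by resistant-mutant resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a bacteriocin target by resistant-mutant resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistseq)
```

## The problem

Two-peptide bacteriocins such as plantaricin JK kill closely related
lactic-acid bacteria by engaging a membrane protein on the target cell and
forcing membrane leakage. When no annotated genome exists for the sensitive
strain, the receptor can still be found genetically: select spontaneous
resistant mutants, sequence them together with the wild type, assemble the
wild-type reads into a crude draft, and look for genes that accumulate
independent mutations across resistant isolates. The difficulty is that a
crude short-read draft is full of consensus errors — mostly in repeat-rich,
low-coverage regions — and every such error shows up as a spurious
"polymorphism" when mutant reads are compared against it.

`resistseq` implements that whole discovery procedure as testable code: a
polymorphism caller over a k-mer seed-and-extend mapper, the two-stage
false-positive exclusion scheme (self-comparison against the wild type and
assembly-coverage flags) plus a depth/allele-fraction/strand verification
step, codon-level consequence annotation, transmembrane localization, and
MIC fold-resistance estimation. Because the study's raw reads are not
public, every input can be generated synthetically with known ground
truth, so the pipeline's claims are tested as recovery properties rather
than asserted.

## The synthetic study

`build_genome()` produces the default desk-scale scenario: 50 kb over 5
contigs (the full study operated on a 1.59-Mb, 243-contig draft; the
reduced scale keeps the statistical structure while making every test
cheap), ~0.6 genes/kb of random protein-coding genes, and pairs of
near-identical (97%) repeats that later corrupt the draft consensus. One
contig carries the engineered focal gene: 1,833 nt encoding a 610-residue
protein placed at positions 2209–4041, so all coordinate arithmetic of the
study's difference table carries over unchanged.

The focal gene is engineered at codon level:

* codon 104 is CGA and codon 395 is TGG, so single transitions create
  premature stops (truncations after residues 103 and 394);
* codon 177 is TTC inside a TT run; inserting one T shifts the frame such
  that the first shifted-frame stop terminates the product after residue
  190. The downstream sequence of the real gene being unpublished, codons
  178–191 are chosen so the shifted frame is stop-free through codon 190
  and stops at 191 — the printed truncation length is therefore a property
  of the engineered fixture, validated on it;
* codons 377/387/425/428 carry the residues whose substitutions the study
  observed;
* the encoded protein follows a designed 12-transmembrane-helix
  architecture (see below), hydrophobic cycles inside helices and mildly
  hydrophilic cycles in loops.

Ten mutant strains (JK1–JK6, JK8–JK11) receive the seven focal mutations
with the study's sharing pattern (three strains share the frameshift, two
share one substitution) plus 0–3 random background substitutions each, for
1–5 mutations per strain.

`simulate_reads()` samples fully contained 250-nt paired-end fragments
(insert 500 ± 50 nt) at 50× with i.i.d. substitution errors at 0.5%.
Sequencing indels are deliberately omitted so any indel evidence in a
pileup is attributable to a genomic variant. One consequence of sampling
fully contained FR pairs on a *linear* contig is that positions within
about one insert length of a contig end are covered almost exclusively by
one strand (left mate windows are always forward, right windows always
reverse); in a real library fragments span contig junctions, so this is a
simulation artifact, and the default mutation placer keeps background
mutations `insert + read length` (750 nt) away from contig ends. This is
what the tests mean by "callable" positions: passing them shows the
pipeline recovers mutations in the regime the study verified (interior,
high-coverage, strand-balanced sites), not that edge-proximal calls would
verify.

`emulate_crude_assembly()` does not assemble; it emulates the *failure
mode* that matters: repeat intervals and a 3% random fraction of positions
are assigned assembly coverage 1–5× and consensus errors are injected
there at 1% per position, with the true per-position coverage track and
the error manifest emitted. The focal gene region is kept out of the
low-coverage band, mirroring the well-covered target region of the study.
What this emulation does **not** capture: chimeric contigs, collapsed
repeat copy-number errors, indel-type consensus errors, and coverage that
correlates with GC content.

## Mapping and calling

The mapper is a plain seed-and-extend design: all 21-mers of the draft are
indexed; each read (both orientations) votes with exact seed matches for a
(contig, diagonal) locus; the winner is verified ungapped, and when seed
diagonals disagree by one, with a scan allowing a single 1-bp indel. At
most 5 mismatches per 250-nt read are accepted. Ties between loci (exact
repeat copies) clear the `unique` flag, and pileups drop non-unique
alignments by default — the pipeline's analogue of distrusting
repeat-confounded evidence. On small genomes the mapper is tested against
a brute-force all-positions alignment oracle.

Calling is deliberately generous (`min_alt_fraction = 0.8`,
`min_depth = 10`) so that the *filter* stage, not the caller, is the
decision point — the published thresholds of the original discovery tool
are not documented, so these defaults are declared, not inferred. Indels
are left-normalized VCF-style (drop the shared trailing base, prepend the
preceding reference base), which places the engineered TTC→TTTC insertion
at the anchor before the T run; the codon of a frameshift is the codon
containing the first inserted/deleted base, which reproduces the
published "177F-frameshift" arithmetic. Sites with alternate fraction
0.2–0.8 are not called: the organism is haploid and sub-clonal signal is
treated as absence.

Two details matter for indel allele fractions in homopolymer runs.
First, the mapper falls back to its edit-aware comparison whenever the
ungapped score is beatable (two or more mismatches), so an indel within a
few bases of a read end — too close to leave seeds on a second
diagonal — is still recognized. Second, evidence anchored at different
run positions is pooled after normalization, and the fraction's
denominator counts *informative* reads only: reads spanning the entire
run plus one flanking base (computed from per-position alignment-start
counts). A read ending inside a TT run cannot distinguish TT from TTT
and would otherwise dilute a true insertion's fraction below the
verification threshold.

## Filtering

`apply_filters()` applies three rules in the study's narrative order and
attributes each exclusion to the first rule that fires, so the
11 + 11 → 36 accounting is well-defined:

1. **wild-type shared** — also present when wild-type reads are compared
   with the assembly built from them: an assembly error, not a mutation;
2. **low-coverage shared** — assembly coverage ≤ 5× *and* shared by ≥ 2
   mutant strains (a low-coverage difference private to one strain is not
   excluded by this rule);
3. **verification** — depth ≥ 20, alternate fraction ≥ 0.9 ("90–100% of
   the reads"), and a two-sided exact binomial(0.5) test on
   forward/reverse alternate support not rejected at α = 0.01. The
   source describes strand balance only qualitatively ("equally
   represented"); the binomial test is a declared operationalization and
   the policy object makes it swappable. The depth floor of 20 is scaled
   to the desk simulation (the study verified at 154–484×); it is a
   declared choice. Note an exact α = 0.01 test rejects a true site about
   once per 100 sites — a genuinely stochastic element of any such
   filter.

The 58-record packaged fixture reproduces the study's difference report:
the 36 retained rows carry the printed contig labels, positions, assembly
coverages, strain-presence matrix and annotation strings; the 22 excluded
rows are synthesized (their individual positions were not printed) with
the correct counts and flag structure, and the two exclusion classes are
disjoint (whether they overlapped in the study is not stated). Two print
quirks are preserved: one retained row has no strain mark and one has no
coverage value (stored `NA`; the low-coverage rule treats `NA` as
not-low, since it cannot assert unreliability).

## Consequences and topology

Gene models are 1-based inclusive; codon index is
`floor((pos - start)/3) + 1` on the forward strand and the mirrored form
on the reverse. ORF discovery (start codons ATG/GTG/TTG, stops
TAA/TAG/TGA, translation table 11) exists to show gene models can be
derived de novo; generated genomes place an in-frame stop directly
upstream of each gene so ORF bounds are exact, and gene models can always
be supplied via GFF3 instead.

Truncation lengths are computed by translating the mutated coding
sequence to its first stop, so nonsense and frameshift effects share one
definition (`truncation_after` = residues before the premature stop). A
compensating indel pair that restores frame before any shifted stop is
flagged `in_frame_restored` rather than assigned a truncation.

Transmembrane prediction uses the Kyte–Doolittle scale with the classical
parameters (window 19, threshold 1.6, minimum run 15, runs > 30 split at
their internal minimum) — declared because the study's tool is
proprietary. The engineered 12-helix architecture places helix boundaries
so the published localizations hold: truncation after 103 falls between
helices 2 and 3 (10 helices removed), 190 inside helix 5 (7 removed), 394
exactly at the end of helix 10 (2 removed, reading "after TM helix 10");
substitutions 377/387 sit in helix 10 and 425/428 in the extracellular
loop between helices 11 and 12 (N terminus cytoplasmic, sides
alternating). Prediction on the engineered protein recovers all 12
helices within ±2 residues; localization statements are made against the
designed intervals, which can also be supplied directly, so they do not
inherit the predictor's ±2 boundary jitter. A removed helix is one whose
*start* lies beyond the truncation point — a helix cut mid-length counts
as present, matching the published counts.

## MIC assay

Inhibition is `1 − (OD − blank)/(growth − blank)` clamped to [0, 1]; the
MIC is the 50% crossing interpolated linearly in log2 concentration (the
assay is a two-fold ladder, so half-step accuracy is the natural
contract; the study reports "about" values). Censoring is explicit:
curves that never reach 50% give `">top"`, fully inhibited plates
`"<bottom"`, and censored values propagate as directional bounds, never
as silent numbers. The generator uses a Hill curve with coefficient 4 —
close to all-or-none across one dilution step, as observed in such
assays — crossing 50% exactly at the true MIC, plus Gaussian OD noise
(σ = 0.02). Replicate spread is reported as the half-range over replicate
ratios to one significant figure, a declared reading of the study's
"± " notation, which is not defined there. The wild-type scenario MIC is
0.5 nmol/L and the default mutant scenario 600-fold higher — scenario
parameters taken from the study's reported scales, not measurements
reproduced here.

## Problem sizes and determinism

The default test scenario is the 50-kb/5-contig genome at 50× over 11
strains (~1.1 × 10^5 reads end to end); the reduced pipeline tests use
20 kb at 30×; MIC recovery uses 200 simulated plates. Every generator
consumes an explicit seed through an RNG scope that restores the caller's
RNG state, so identical seeds give byte-identical outputs and a report's
configuration hash identifies a run. The focal gene sequence itself is a
package constant (fixed internal seed) so codon-level tests are
scenario-independent.

## Known limitations

* The mapper handles at most one 1-bp indel per read and no clipping;
  reads overhanging contig ends are left unmapped. This matches the
  variant classes under study (SNVs and 1-bp indels) but not general
  structural variation.
* Consensus-error emulation covers substitutions only.
* The engineered gene validates codon-identity and truncation claims on
  the fixture, not on the unpublished real sequence; likewise helix
  boundaries are designed, not inferred from the real protein.
* The strand-balance verification is exactly sized, so on any run it can
  exclude a true site with probability ≈ α per site; the packaged
  scenario documents this rather than hiding it.
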