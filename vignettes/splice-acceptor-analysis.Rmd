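---
title: "Splice-acceptor variant consequence analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-acceptor variant consequence analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetriage)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design decisions taken where more than
one convention was defensible.

## The problem

A single-nucleotide substitution at the last base of an intron (c.X-1G>A in
HGVS terms) destroys the essentially invariant AG of a 3' splice acceptor.
The spliceosome then either uses a nearby cryptic AG or skips the exon, and
each choice rewrites the mRNA downstream of the lesion. For a mismatch-repair
gene such as MSH2 this is the difference between a benign intronic variant
and a Lynch-syndrome allele, so the pipeline's job is to enumerate the
plausible aberrant transcripts, translate each to its premature termination
codon (PTC), and put numbers on everything a wet-lab minigene assay would
later measure.

## Acceptor scoring

Acceptor strength is scored against a 16-position nucleotide frequency
matrix: positions 1–8 model the polypyrimidine tract (T/C rich, the −3
position strongly C), positions 9–10 the invariant AG, and positions 11–16
the first exonic bases with G favoured at +1. The raw score of a window is
the summed log frequency of its bases, affinely rescaled so the per-position
modal window scores exactly 100 and the anti-modal window 0. Two properties
follow by construction and are enforced by tests: the scale maximum is
attained only at the consensus, and replacing any base by a lower-frequency
one can never raise the score.

The matrix shipped here is written from the canonical metazoan acceptor
consensus and is deliberately self-consistent rather than a clone of any
published tool's matrix. Scores printed by external predictors (HSF, MaxEnt,
SpliceAI, NetGene2 and the like) are treated as *inputs*: the reproducible
content of a splice-prediction table is the delta arithmetic

$$\Delta = 100 \cdot \frac{s_{mut} - s_{wt}}{|s_{wt}|},$$

with the absolute value in the denominator so that a free-range (log-odds)
baseline of −2.15 rising to 5.8 is reported as +369.77%, a gain — the only
convention consistent with how such tables are printed. Loss is called at
Δ ≤ −10% and new-site gain at Δ ≥ +10% at non-canonical positions; the ±10%
defaults follow the common interpretation convention for consensus-value
tools and are configurable because published analyses state calls, not
cutoffs.

## Cryptic-site scanning and transcript reconstruction

After an acceptor loss, every AG dinucleotide within the scan window is a
candidate replacement. The default window — 100 nt into the intron and 25 nt
into the exon — covers both events observed in the motivating case (a 51-nt
intronic site and a junction-spanning site) with generous margin. Each
candidate is scored with its own 16-nt context and candidates are ranked by
score, ties broken by proximity to the canonical junction. In wild-type
context the canonical AG's own dinucleotide is reported but excluded from
new-site candidacy; in mutant context every AG is a candidate, including the
AG a G>A substitution can create from the mutated intron-terminal base plus
an exon-initial G.

Reconstruction is purely positional: an AG whose G lies k bases into the
exon truncates the exon's first k bases (nt delta −k, `c.<first>del` when
k = 1); an AG d bases from the intron end retains the last d intronic bases
(nt delta +d, `c.<last>_<first>ins<d>`), carrying the variant base when the
retained segment includes it. Exon skipping is available behind a flag
rather than by default, because a skip is always *constructible* — reporting
it unconditionally would bury the scored candidates; when no candidate site
exists it is the forced outcome. The ranking deliberately stops short of
adjudicating which isoform "wins": splicing assays routinely show several
products at once, so all candidates are reported with their scores.

## Translation, fs\*N bookkeeping and NMD

Each isoform is translated from c.1 in the standard genetic code. The first
residue differing from the normal protein is the anchor; the walk continues
in the new reading to the first stop. Under the HGVS frameshift convention
the anchor counts as position 1 and the stop as position N, so the truncated
protein has

$$\text{length} = \text{first\_codon} + N - 2$$

residues (the stop is not counted). This is the bookkeeping that turns
p.Val265Leufs\*9 into a 272-aa product and p.Val265Asnfs\*15 into 278 aa,
and a dedicated oracle test verifies on a thousand randomized genes that the
formula never disagrees with literally counting residues off the mRNA.

Three edge conventions are worth stating. When the anchor codon is itself a
stop, the event is a nonsense substitution (p.Ref\<pos\>\*), not fs\*1. When
the nt delta is a codon multiple and the downstream protein realigns
cleanly, in-frame insertion/deletion nomenclature is emitted and no fs\*N is
claimed. But an in-frame insertion whose inserted residues contain a stop
*is* rendered fs\*N: a 51-nt retention is in-frame arithmetically, yet when
the retained acceptor context contributes a TAA at inserted codon 15 the
biological outcome is a truncated protein, and the fs\*15 notation with
length 265 + 15 − 2 is the one that matches how such events are reported.
Transcripts with no stop before their end are flagged as extensions
(`no_ptc`), never raised as errors.

NMD is called by the classic boundary rule: a PTC more than 50 nt upstream
of the final exon–exon junction (junctions recomputed on the aberrant exon
structure) predicts degradation; single-exon transcripts are never
substrates. The 50-nt default is configurable since the rule is a
population-level heuristic.

## Minigene arithmetic

A splicing minigene is modelled as an ordered segment list (exons, intron
parts, vector flanks) with the transcribed vector contribution summarised as
`flank_total` — published constructs state the total (160 nt here) without
its 5'/3' split, and only the total affects band sizes, so the split is
stored but defaults to all-5'. The wild-type RT-PCR product is flank plus
exonic nucleotides; every aberrant isoform shifts it by exactly its nt
delta, a property tested on randomized constructs. Junction k-mers for
Sanger primer checking are sliced from the segment sequences; restriction
sites are carried as labels only.

## Clinical rule engines

*MSI.* The five-marker NCI panel (BAT25, BAT26, D2S123, D5S346, D17S250) is
classified MSI-H at ≥ 40% unstable markers — the stated threshold in the
motivating study. The MSS/MSI-L boundary (any instability below 40%) follows
the Bethesda convention, which the study leaves implicit. Off-panel markers
are counted with a warning rather than dropped, since panels vary in
practice.

*IHC.* MSH2 dimerises with MSH6 and MLH1 with PMS2, and each dimer is
stabilised by its obligate partner. Loss of MSH2 (with or without MSH6)
therefore implicates MSH2; isolated MSH6 loss implicates MSH6; the MLH1/PMS2
axis mirrors this. When both axes show loss the candidates are ranked by how
much of each dimer is missing. The mapping is total over all sixteen
patterns and exhaustively tested.

*Amsterdam II.* Three relatives with Lynch-spectrum cancer, one of them
first-degree to the other two; two successive generations; one diagnosis
before 50; FAP exclusion and pathology verification. The last two are
attestations accepted as booleans — they are pathology work, not pedigree
arithmetic. First-degree links and generation depth are derived from parent
pointers; when the trio test fails while affected members lack any kinship
information, the criterion is reported indeterminate and the pedigree "not
evaluable" rather than silently failed. The default spectrum is
{colorectal, endometrial, small bowel, ureter, renal pelvis} and is
configurable.

## The synthetic-data generator

`make_toy_gene()` emulates exactly the structure the pipeline assumes: a CDS
prefix of full codons (264 in the MSH2-like preset, so the studied junction
is c.793), a target exon opening GTTGCA (valine at the junction codon, so
the junction-spanning AG yields a Val→Leu anchor), the acceptor context
`ttaattttag` at the studied intron's 3' end, a cryptic AG planted at a
configurable retained-length offset (51 in the preset) with AAT as the first
retained codon (asparagine), and stop codons engineered so each aberrant
reading terminates at a prescribed new-frame codon (9 for the truncation, 15
for the retention in the preset — the latter supplied naturally by the TAA
inside the acceptor context when the retained length is a codon multiple).

Generation samples background uniformly over A/C/G/T, plants the motifs,
then repairs collisions by flipping offending bases to C — a repair that can
never create an AG or a stop, so one pass per constraint converges. Planted
positions are immutable; a draw that would need to change one is discarded
and re-sampled (bounded at 100 attempts before a generation error, reached
only for structurally infeasible specs, which the spec constructor mostly
rejects up front). Every accepted gene passes `audit_toy_gene()`, which
re-derives all promised properties from the sequences alone — the AG census
of the scan window in both wild-type and mutant context, the motif plants,
and the first-stop positions of all three readings. Generation is
deterministic given the spec (seed included) and leaves the caller's RNG
stream untouched.

What the toys do *not* emulate: real splice-site strength distributions
(background is uniform where real introns are pyrimidine-skewed), branch
points and polypyrimidine-tract quality, multi-isoform quantitative usage,
and genomic-scale intron lengths (non-studied toy introns default to 200
nt). Passing tests on toys therefore demonstrate coordinate and bookkeeping
correctness, not predictive accuracy on real genes — for real work the user
supplies the actual reference sequence as the gene model.

The clinical fixture generator builds a four-generation pedigree shaped like
a published Lynch family (nine colorectal diagnoses across two successive
generations, several before age 50), an MSI record with 2–5 unstable
markers, and the two observed IHC patterns; all three are verified against
their own classifiers in the test suite.

## Numerical and interface choices

- Internal coordinates are 0-based half-open; HGVS surfaces are 1-based.
  Conversion is confined to the gene-model module so off-by-one drift has a
  single home.
- Only plus-strand gene models are accepted; minus-strand input errors
  rather than being silently reverse-complemented.
- UTR positions (c.-N, c.\*N), duplications, inversions and delins are
  outside the supported HGVS subset and fail with "unsupported nomenclature".
- Percent changes are kept at full precision and rounded only at
  presentation (two decimals).
- Scoring windows truncated by sequence ends score NA and rank last rather
  than being padded.
- `percent_change` with a zero baseline is an error (undefined), not an
  Inf.
- The `ins51bp` dialect seen in print is normalised to standard `ins51` on
  output.

## Problem sizes in the test suite

The property suites run on sizes chosen to finish comfortably on a laptop:
the formula-vs-walk translation oracle covers 1,000 randomized toy genes,
the scanner-vs-brute-force oracle 1,000 random windows, and the remaining
property loops 20–100 cases each; the full suite completes in under two
minutes.

## Known limitations

Donor-site (5'ss) consequences are out of scope, as are branch-point
modelling, isoform usage ratios, multi-intron compound events, liftover and
multi-transcript gene databases. The shipped matrix is a reasonable
consensus model, not a trained predictor — its scores order sites sensibly
but should not be compared numerically against published tool outputs. The
PREMM-style risk models are not implemented (their coefficients are not
public in the material this package follows); supplied scores can be carried
as annotations only.

## Session info

```{r}
sessionInfo()
```
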