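# splicetriage

Desk-side consequence analysis for 3' splice-acceptor variants in coding
genes, plus the rule-based clinical classifiers used to triage Lynch-syndrome
families. The package grew out of the work-up of the MSH2 intron-4 acceptor
variant **c.793-1G>A**: its functions reproduce, as ordinary tested code,
every arithmetic step of that analysis — splice-site score deltas,
cryptic-acceptor discovery, aberrant-transcript reconstruction, frameshift
nomenclature and truncated-protein lengths, minigene RT-PCR band prediction,
and the MSI / IHC / Amsterdam II rule engines.

## What it computes

**Acceptor scoring and deltas.** A 16-nt position-weight window (10 intronic
nt covering the polypyrimidine tract and invariant AG, 6 exonic nt) is scored
consensus-value style on 0–100. The effect of a variant is the percent
change ΔCV = 100 · (CV_mut − CV_wt) / |CV_wt|, with loss called at ≤ −10%
and gains (at non-canonical positions) at ≥ +10%. Printed scores from
external predictors can be fed through the same arithmetic: scores of
86.74 → 58.87 give ΔCV = −32.13%; 10.35 → 1.6 give −84.54%; a free-range
score of −2.15 → 5.8 gives +369.77% (a new-site gain).

**Consequences of acceptor loss.** When the canonical AG is destroyed, every
AG in a configurable window (default 100 nt into the intron, 25 nt into the
exon) is a candidate replacement. An AG whose G lies k bases into the exon
truncates the exon by k (`c.<first>del` for k = 1); an AG d bases from the
intron end retains those d intronic bases (`c.<last>_<first>ins<d>`). Each
isoform is translated from c.1 to its premature termination codon: for
p.Val265Leufs\*9-style annotations the truncated protein is
first_codon + N − 2 residues (265 + 9 − 2 = 272 aa; fs\*15 gives 278 aa),
and the 50-nt rule flags NMD substrates.

**Minigene planning.** An exon–intron–exon construct (147 + 1,708 + 150 =
2,005 bp insert in the motivating case) with a 160-nt transcribed vector
flank yields a 457-bp wild-type RT-PCR product (297 bp of it gene-derived);
every aberrant isoform shifts that by exactly its nt delta (456 bp and
508 bp here). Junction k-mers are emitted for Sanger verification.

**Clinical triage.** The NCI five-marker MSI panel classifies MSI-H at ≥ 40%
unstable markers; IHC loss patterns are mapped to the causal mismatch-repair
gene through the MSH2–MSH6 / MLH1–PMS2 heterodimer logic; Amsterdam II is
evaluated on pedigree tables with derived first-degree relationships and
generation depth.

**Synthetic data.** `make_toy_gene()` builds fully audited toy genes with a
planted cryptic AG, a GTTGCA junction codon and engineered first stops, so
the entire pipeline is testable without reference downloads;
`mshlike_gene()` is the preset that mirrors the motivating MSH2 case.

## Worked example

```r
library(splicetriage)

gene <- mshlike_gene()
report <- run_pipeline(gene, "c.793-1G>A")
report
#> <splice_report> c.793-1G>A
#>   canonical acceptor: 82.52 -> 64.30 (-22.08%), site_loss
#>   2 aberrant isoform(s):
#>     exon_truncation    -1 nt  c.793del           p.Val265Leufs*9        272 aa  [NMD]
#>     intron_retention  +51 nt  c.792_793ins51     p.Val265Asnfs*15       278 aa  [NMD]
#>   predicted RT-PCR bands: a=457 bp, b=456 bp, c=508 bp
```

The G>A substitution at the intron's last base breaks the canonical acceptor
(score 82.52 → 64.30 under the shipped matrix, a −22% loss call). Two
replacement AGs exist: the junction-spanning one (the mutated `a` plus the
exon-initial `G`), which trims one base off the exon and shifts the frame to
a stop nine codons later (272-aa product), and a cryptic AG 51 nt into the
intron, which retains 51 intronic bases whose fifteenth new codon is a stop
(278-aa product). Both PTCs sit more than 50 nt upstream of the final
junction, so both isoforms are flagged NMD substrates. The predicted bands
(457/456/508 bp) are what an RT-PCR gel of the corresponding minigene would
show. `tidy(report)` returns the isoform table, `glance(report)` a one-row
summary, and `autoplot(report)` the band schematic.

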