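---
title: "Methods: the somatic novel-variant discovery funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the somatic novel-variant discovery funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticfunnel)
```

This vignette is the package's account of its models and procedures: what is
computed, under which assumptions, which knobs matter, and what the synthetic
cohort does and does not emulate.

## The problem

A tumor sample and a matched normal (here: a breast-tumor-derived cell line
and the patient's PBMCs) are exome sequenced and variant-called upstream of
this package. Candidate *somatic, novel, functional* mutations are then
obtained by set algebra and annotation: remove calls shared with the normal
(assumed inherited), remove calls present in public variant catalogues
(assumed known polymorphisms or previously observed mutations), keep exonic
calls that change the protein, and interpret the surviving genes via a cancer
gene census and pathway over-representation. The package re-implements that
whole funnel from the VCF level down, deliberately *without* any statistical
somatic-caller model: subtraction is exact key matching, as in the original
design.

## Variant identity

Everything downstream keys variants by `(chrom, pos, ref, alt)` after
left-normalization, so representation differences can never leak into set
operations. Left-normalization iteratively truncates shared trailing bases
(extending one reference base leftward whenever an allele would empty) and
then trims shared leading bases while both alleles exceed one base. This
yields the unique parsimonious left-aligned representation; SNVs are fixed
points and the operation is idempotent. The test suite checks the
implementation against an independent brute-force oracle that enumerates
every equivalent representation in a 50 bp window and picks the minimal-
length, minimal-position one. Symbolic alleles (`<DEL>`, breakends) and
alleles containing `N` are flagged and passed through untouched rather than
dropped — they cannot be normalized against a literal reference slice.

Multi-allelic records are decomposed one ALT per row before anything else,
and chromosome names are compared verbatim (the study's tables use bare
`22`-style names).

## The load-time quality gate

Calls are gated on total depth > 50, variant-supporting depth > 15 and caller
p-value < 0.01 — the thresholds the upstream caller filter used — as a
configurable predicate (`variant_gate()`), defaulting ON. Records missing the
gated fields pass with a warning: fixtures and third-party VCFs often lack
caller statistics, and silently dropping them would corrupt counts.

## QC metrics

Ti/Tv is computed over SNVs only (transitions A↔G, C↔T; eight transversion
types); MNVs and indels never contribute, and zero transversions yield an
*undefined* ratio rather than infinity. dbSNP concordance uses **all** loaded
variants in the denominator, not only SNVs — the wording of the source QC
("variants") does not restrict the denominator, and the choice is recorded
here because it changes the number. Off-target counting asks whether the
first REF base falls inside any capture interval; BED input is converted from
0-based half-open to the package's 1-based inclusive convention on read.

## Annotation

Transcript models are RefSeq-like: genomically ordered exons, genomic CDS
bounds, and the spliced CDS sequence supplied explicitly (TSV + FASTA). Region
classes are resolved across transcripts by the precedence
`exonic = splicing > UTR5 = UTR3 > intronic > upstream = downstream >
intergenic`, reporting the genes of every transcript achieving the winning
class. Two declared defaults the source never states: the splice window is
±2 bp on the intron side (canonical donor/acceptor positions) and the
upstream/downstream windows are 1 kb from the transcript ends. Both are
package constants, chosen to match common annotator behavior, not inferences
from the study.

Coding consequences map the genomic change onto the spliced CDS
(reverse-complementing alleles on minus-strand models), translate the
affected codon with the standard genetic code (stop rendered `X`), and
classify into synonymous/nonsynonymous SNV, stopgain, stoploss, and
frameshift/nonframeshift insertion/deletion by length mod 3. cDNA strings use
the `c.<ref><pos><alt>` dialect of the study's tables (e.g. `c.G689T`,
`p.S230I`) rather than strict HGVS, because those strings are the comparison
surface. Strand correctness is property-tested with a mirrored minus-strand
transcript carrying the identical CDS.

## The funnel

Stage order and semantics: germline subtraction by key; then an *ordered*
catalogue cascade (dbSNP-like `avsnp150` first, then nine further
catalogues). "Passing" a catalogue means being **absent** from it — the
novelty-keeping reading is forced by the published stage counts (a 16,217 →
1,098 drop at the dbSNP stage can only be removal of members). Intermediate
survivor counts depend on catalogue order by design; the final novel set does
not, which is property-tested. Catalogue matching is allele-exact on
normalized keys (whether the original analysis matched loci or alleles is
unstated; allele-exact is the default here). Functional filtering keeps
exonic variants and removes synonymous SNVs; gene extraction takes the union
of symbols (uppercased) across variants; the census comparison reports the
intersection with tier breakdown and the Tier-1 percentage at one decimal.

The unexplained drop from 423 extracted genes to the 309-gene list used for
pathway analysis in the source study is **not** derived anywhere: the ORA
stage takes an explicit query-gene-list input (the pipeline default is the
synthetic fixture's own 309-gene list), never a silent subset.

## Over-representation

Gene-level counting: with `n` query genes found in the `N`-gene universe and
`k` of them in a `K`-gene pathway, `p = P(X ≥ k)` for `X ~ Binomial(n, K/N)`,
computed with `pbinom`'s stable tail (verified against direct pmf enumeration
to 1e-12 up to n = 500). Only pathways with `k ≥ 1` enter the BH correction
(matching "hit by at least one gene"; correcting over all pathways is a
switch). Entity-level expansion as done by the Reactome service is out of
scope, which is exactly why the published pathway p-values are not
reproduction targets — only the bookkeeping (178 of 309 genes found, 695
pathways hit) is.

## Predictor consensus

Five predictors are normalized through a fixed vocabulary table;
PolyPhen-2's "possibly damaging" counts as damaging (the study's consensus
treats HDIV/HVAR as concordant with damaging calls), configurable. A
unanimous flag requires every supplied method damaging with no unknowns.
Structure-based scores (free-energy changes, hydrogen-bond reports) are
consumed nowhere — they are out of scope.

## Dose–response

Luminescence is normalized to the mean of DMSO control wells
(`100 × raw / mean(DMSO)`). The 4PL model is written in the Prism convention

\[ y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
     {1 + 10^{(\log_{10}\mathrm{IC}_{50} - x)\,\mathrm{hill}}},\qquad
   x = \log_{10}(\text{concentration}) \]

so that an inhibitor has hill < 0, top = plateau at vanishing dose, bottom =
plateau at saturating dose, and the fitted value at `x = log10(IC50)` is the
plateau midpoint (asserted for every fit). Concentrations are treated as
micromolar throughout — the source tables print unitless IC50s, and this is a
documented assumption. Fitting is unweighted Levenberg–Marquardt least
squares (`minpack.lm`), initialized at top = max response, bottom = min
response, log IC50 = median dose, hill = −1, with three jittered restarts on
failure; parameters are unconstrained so the data decide the hill sign.
Monotone-flat responses are rejected ("no dose dependence") rather than fit.

**Precision of IC50 recovery.** Under the fixture's exact design — 8 half-log
doses in triplicate, 5% multiplicative Gaussian noise, true parameters
(100, 5, −1, 0.94 µM) — the Cramér–Rao bound for log₁₀ IC50 with all four
parameters free is ≈ 0.0355 log units, i.e. a median absolute relative IC50
error of ≈ 5.5% for an *efficient* estimator. The unweighted fit achieves a
median of ≈ 7% over 200 replicates (relative weighting improves it only to
≈ 6.4%), so the recovery test asserts near-efficiency relative to the bound
computed in-test rather than an absolute constant the design cannot deliver.
Single-plate recoveries scatter with ≈ 8% SD around the truth, comfortably
inside the 10% band used for the seeded fixture check most of the time;
summaries that need a tighter estimate should take the median over replicate
plates, as the reproduction script does.

## The synthetic cohort

`generate_cohort()` is first-class, tested code, not a test crutch. It lays
out ~430 non-overlapping multi-exon genes (three 120-codon exons by default;
a quarter on the minus strand) on one synthetic chromosome, each with a valid
ATG…stop ORF, 60 bp UTRs, 150 bp introns, and 1.5 kb of padded capture
target. Four transcripts reproduce worked examples from the study's
validation table, including a receptor-gene model whose codon 230 is `AGC`
at CDS 688–690 in exon 6, so the planted G>T yields `c.G689T` / `p.S230I`.

Planting is count-driven: the default profile *is* the study design (32,917
and 30,939 calls, 16,700 shared, 15,119 dbSNP-like members, 115 other-catalogue
members, 983 novel split 401 non-exonic / 91 synonymous / 325 functional SNV /
166 indels across exactly 423 genes with 68 multi-hit extras, census overlap
21 with 19 Tier 1 among 723 census entries), and the generator reproduces
every one of those counts for *any* seed — the seed moves positions, alleles
and decoys, never the composition. Choices not fixed by the study, made once:

* the 401 non-exonic novel variants are split uniformly across intronic,
  splice-site, UTR5, UTR3, upstream and downstream classes (the study only
  says "intronic, splice, 5UTR, 3UTR, etc.");
* bulk substitutions are transition-biased (73%) so the cohort's own Ti/Tv
  lands near the coding-exome-typical ~2.6 the study reports;
* a fraction of shared germline indels is planted in engineered homopolymer
  runs and written **un-left-aligned** in the tumor VCF but normalized in the
  normal VCF, so germline subtraction genuinely exercises normalization;
* per-call depths and p-values are drawn to pass the quality gate, since the
  study applied that gate upstream of the published totals;
* normal-exclusive calls (14,239) are generated and then unused downstream,
  keeping the inputs realistic;
* the default master seed is 230 — the mutated codon number, memorable and
  arbitrary.

What the synthetic cohort does **not** emulate: read-level errors (no
FASTQ/BAM), allele-frequency structure, linkage, realistic gene lengths and
density, population catalogue frequencies (membership is binary), or any
property of the real deposited exomes. Passing the planted-count tests
therefore demonstrates the *pipeline arithmetic and bookkeeping* are exact,
not that the biology of the original samples is recovered.

Problem sizes used by the test suite: the full default profile (~64k calls)
is generated and funneled in well under a minute; the planted-set recovery
property is checked across ten seeds; the IC50 recovery study uses 200
replicate plates. The QC fixtures are dedicated small sets: a 3,700-SNV
set with 2,700 transitions (Ti/Tv exactly 2.7) and a 1,000-variant set with
962 keys planted in the mock dbSNP (96.2%).

## Degenerate inputs and numerical notes

Empty variant sets yield zero-count reports with undefined (NA) ratios, never
division errors; zero transversions flag Ti/Tv undefined; an empty capture
set counts everything off-target with a warning; an empty census table is an
error. BH ties are broken by pathway id for deterministic output ordering.
Normalization at position 1 requiring a left extension is a reported boundary
error. All generator randomness flows from a single integer seed and
regeneration is byte-identical, which the suite asserts on written files.

## Known limitations

* Region classification and catalogue matching use the first REF base of an
  indel; a deletion spanning an exon boundary is classified by its anchor.
* `c.`/`p.` strings for indels are simplified (positions and fs/del/ins tags,
  not full HGVS normalization).
* No ncRNA transcript classes and no population-frequency thresholds.
* The ORA stage reproduces gene-level Reactome-style bookkeeping, not
  entity-level statistics or topology-aware corrections.
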