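---
title: "Enrichment of disease-associated variants in regulatory elements: methods"
author: "regvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment of disease-associated variants in regulatory elements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(regvar))
```

## The scientific problem

Most disease-associated genetic variants fall outside protein-coding
sequence, where their interpretation depends on regulatory context:
promoters, enhancers, insulators, methylated regions, histone-modification
domains, chromatin interaction zones, protein binding sites and open
chromatin. A natural first question is descriptive — how densely do
disease variants populate each kind of regulatory element? — and the
natural second question is inferential: are variants of a given disease
category (Mendelian, complex, cancer germline, cancer somatic)
*over-represented* in a given element class relative to the genomic
background, and does that enrichment survive controlling for the very
different allele-frequency spectra of disease versus background variants?

`regvar` implements that analysis as a reusable, tested pipeline with
four layers.

## Interval layer

Regulatory tracks are merged interval sets (`RegulatoryTrack`), built on
`GenomicRanges`. Coordinates follow the BED convention at the file
boundary (0-based, half-open) and GRanges conventions internally
(1-based, closed); the conversion happens only in `readBed()` /
`writeBedTrack()`. Two choices matter:

* **Abutting intervals merge.** Track lengths are union lengths, and two
  intervals separated by a zero-width gap cover the same bases as their
  union, so `[10,20) + [20,30)` becomes one 20-bp interval.
* **Genomic region classes may overlap.** From gene models we derive
  seven classes — coding exon, 5'UTR, 3'UTR, intron, upstream and
  downstream 2,000-bp flanks, and intergenic. Each class is computed
  independently from its own definition (introns are each transcript's
  span minus its exons; UTRs are exonic sequence outside the CDS, split
  by side strand-awarely; flanks are strand-aware and clipped at
  chromosome ends). A base can belong to several classes — an exon of one
  gene can sit in the intron of another — and row percentages of the
  overlap matrix can therefore sum to more than 100%. Only the intergenic
  class is defined by complement (genome minus gene bodies and flanks).
  For fully coding annotations the seven classes jointly cover every base
  of the genome; transcripts without a CDS contribute no UTR class, so
  purely noncoding annotations can leave exonic bases covered only by
  their flanking classes.

Unstranded gene records default to the + strand with a warning, and bare
chromosome names gain a `chr` prefix unless disabled.

## Density layer

For a track of length $L$ bp containing $n$ unique disease variants the
density is reported as disease variants per million base pairs,

$$\mathrm{DVPM} = 10^6 \, n / L .$$

Variants are treated as points: membership of an interval is decided by
position alone, ignoring allele length, so indel span conventions cannot
change counts. The float DVPM is canonical in machine-readable output; a
rounded integer is also reported, with halves rounded away from zero.
Published density tables mix truncation and rounding across rows (one row
derives from 472.7 yet prints 472, while another derives from 67.7 and
prints 68); we standardize on rounding, which reproduces all rows except
the one truncated case, where we differ by 1.

Per-class density counts deduplicate a variant only in the row total: a
variant inside a track that lies in two overlapping genomic classes is
counted in both class columns but once in the total, which is why class
columns can sum to more than the total.

## Enrichment layer

For a disease set and a control set, each variant is classified as within
or outside a track, giving the 2×2 table with cells $DMW, DMO$ (disease
within/outside) and $DCW, DCO$ (control within/outside). The enrichment
statistic is the odds ratio

$$\mathrm{OR} = \frac{DMW/DMO}{DCW/DCO},$$

reported with its natural logarithm and the standard error of the log-OR,

$$\mathrm{SE} = \sqrt{\tfrac{1}{DMW} + \tfrac{1}{DMO} + \tfrac{1}{DCW} + \tfrac{1}{DCO}},$$

and tested with the plain Pearson chi-squared statistic on one degree of
freedom — no Yates continuity correction, matching the test the analysis
design names. Numerical policy:

* **Zero cells.** The default policy flags the result (`Inf`/`NaN`
  odds ratio, non-finite log-OR/SE) rather than silently altering the
  statistic. An optional Haldane–Anscombe `+0.5` correction exists for
  plotting pipelines but is never on by default.
* **Zero margins.** A table with an empty row or column has no testable
  independence structure; the statistic is reported as 0 with p = 1 and
  a warning.
* p-values are kept at full precision; significance thresholds are
  applied downstream.

The control group for this layer is the *genome variant background*: the
full SNP panel minus every disease-associated variant
(`subtractVariants()`), so disease and control are key-disjoint by
construction and the table margins equal the set sizes.

Error bars for forest-style displays are emitted as lnOR ± SE columns;
the report layer chooses the multiplier (default ±1 SE).

## Matched-null layer

Disease variants are systematically rarer than random SNPs, and rarity
correlates with functional annotation, so the background comparison can
confound enrichment with allele-frequency structure. The matched null
removes that confounder:

1. Bin the disease set's allele frequencies. The default edges
   $\{0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 1\}$ are dense at
   the rare end, reflecting disease-variant site-frequency spectra; the
   original analysis did not state its binning, so the edges are
   configurable. Variants with missing AF form their own stratum rather
   than being dropped — control groups must be *equal size*.
2. Draw `n_sets` (1,000 by default) control sets from the background,
   each matching the disease histogram **exactly** per bin: sampling is
   without replacement within a set and independent across sets. A pool
   bin smaller than its quota raises a capacity error naming the bin and
   shortfall.
3. For each replicate, build the 2×2 table of disease versus that control
   set, record the odds ratio and its chi-squared p-value.
4. Summarize: the **median OR** over finite replicate ORs (the count of
   non-finite replicates is reported), the fraction of replicates
   significant at `alpha` (default 0.05), and a **q summary**.

The published q-value procedure over 1,000 replicate p-values is
ambiguous, so the package declares its interpretation rather than
reconstructing one: Benjamini–Hochberg adjustment over the replicate
p-value list, reporting the largest adjusted value among replicates whose
raw p is below `alpha` (1 if none). It is monotone, conservative and
reproducible, and it is always reported alongside the raw significant
fraction so readers need not rely on the q alone. Whether the original
analysis matched AF exactly or approximately per bin is also unstated; we
match exactly, which the test suite verifies bit-for-bit.

**Randomness.** One root seed drives each analysis; per-replicate streams
use the i-th value of `sample.int(.Machine$integer.max - 1, n)` drawn
immediately after seeding, so replicate *i* is reproducible in isolation
and results are identical for identical (inputs, seed).

## Consequence and score summaries

Consequence terms and functional scores (VEP, GWAVA, CADD, GERP,
Mutation Assessor) are *inputs*; the package never computes them. The
shipped severity ranking is the 34-term Sequence Ontology ordering used
by Ensembl VEP, stored as an editable TSV; the "severe" block spans
transcript ablation (rank 1) through missense (rank 11), and the top-k
fraction defaults to k = 11. One consequence per variant is assumed;
`reduceToMostSevere()` collapses multi-term annotations to the smallest
rank. Score summaries report the fraction of *scored* variants passing a
threshold (`>=` or `>`), with unscored variants excluded and counted —
the two canonical uses are Mutation Assessor ≥ 1.9 (medium/high
functional impact) and GERP > 0 (evolutionary constraint).

## Synthetic-data generator

Real FANTOM5/ENCODE tracks and curated disease sets are far too large to
ship, and their genome-wide numbers are not reproducible at desk scale.
The generator instead builds scenarios in which the *truth is known*, so
every stage of the pipeline can be validated:

* **Genome and genes.** Non-overlapping genes are placed in equal slots
  per chromosome (guaranteeing disjointness), each with 1–4 exons and an
  interior CDS leaving UTRs at both ends.
* **Tracks.** Intervals with exponential lengths are scattered uniformly;
  the interval count is corrected by $-\log(1-f)$ for union overlap so
  the merged track hits the requested genome fraction, then trimmed to
  the exact target length.
* **Pool.** Uniform positions with unique (position, alleles) keys; AFs
  i.i.d. from a configurable model, default Beta(0.2, 2) — rare-skewed
  like a site-frequency spectrum. The model is configurable so matching
  can be stress-tested under mismatched disease/pool AF shapes.
* **Planted enrichment.** Each disease variant falls inside the target
  track with probability $p = \lambda c / (\lambda c + 1 - c)$ at track
  coverage $c$, uniformly within the chosen side. Then
  $\frac{p/(1-p)}{c/(1-c)} = \lambda$ identically, so the population odds
  ratio against a uniform background is exactly the planted
  fold-enrichment — an analytic oracle for recovery tests. Disease
  variants may collide with pool positions; the pipeline's subtract step
  removes them, mirroring the panel-minus-disease background
  construction.

The default scenario (`syntheticConfig()`) is a 3-Mb two-chromosome
genome, 150 genes, three tracks at 1/2/5% coverage, a 50,000-variant
pool, and four planted disease sets chosen to mirror the qualitative
structure of the real data at roughly one-tenth scale: strong promoter
enrichment for the Mendelian-like (λ = 20) and somatic-like (λ = 10)
sets, a moderate insulator-type enrichment for the germline-cancer-like
set (λ = 10), and a near-null complex-like set (λ = 1.5). These defaults
were fixed once, from the design, and are not tuned.

What the generator does **not** emulate: linkage disequilibrium,
mutation-rate heterogeneity, chromosome-scale sequence context, or any
correlation between AF and position. Passing tests therefore demonstrate
the statistical machinery is correct — not that real tracks or real
variant curation would yield any particular enrichment.

## Validation design and problem sizes

The test suite checks every interval operation against a brute-force
per-base-pair set-arithmetic oracle on toy genomes (≤ 100 kb), the
Pearson statistic against the closed form
$N(ad-bc)^2 / (r_1 r_2 c_1 c_2)$ on 1,000 random tables (to 1e-9), exact
AF-histogram equality of every matched control set across seeds, and
parameter recovery: at 1% track coverage with 2,000 disease variants and
200 replicates, the recovered median OR lies within ±25% of planted
λ ∈ {2, 5, 10, 20}, and under λ = 1 the replicate rejection fraction
stays within three binomial standard deviations of the nominal 0.05.
These sizes keep each property check in the seconds-to-a-minute range
while leaving the binomial sampling bands comfortably narrower than the
effects being detected.

Two caveats worth knowing. At λ = 2 the recovered median OR is dominated
by the placement noise of the single planted disease set (relative SD
about 16% at these sizes), so the ±25% band is a roughly 1.6-sigma
statement conditional on the seed. And with an expected within-track
count of ~20 per replicate, the chi-squared test is discrete and slightly
conservative, so marginal null rejection rates typically land below
0.05 rather than on it; the acceptance script therefore estimates the
test's size by averaging over ten independent null plantings.

## Known limitations

* Variant membership is point-based; long indels spanning a track
  boundary count by their start position only.
* No liftover, no alternate haplotype contigs, no indel normalization,
  no rsID resolution: inputs are taken at face value.
* AF semantics are "alternate-allele frequency as provided" — no folding
  to minor-allele frequency. The matching procedure only needs
  distributional equality, and which population's AF to use is the
  user's choice.
* Matching is on AF only; covariate matching (LD, gene density, distance
  to TSS) is out of scope.
* The q summary is a declared interpretation of an ambiguous published
  procedure, and is labelled as such in the output metadata.
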