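# regvar

Stratified enrichment analysis of disease-associated variants in
regulatory elements.

## What it does, and for whom

Most disease-associated variants are noncoding, and interpreting them
means asking where they sit relative to regulatory element tracks —
promoters, enhancers, insulators, methylation and histone-modification
regions, chromatin interaction zones, protein DNA-binding sites and open
chromatin. `regvar` is for genomicists who have such tracks (BED), gene
models (GFF3/GTF/BED12), and categorized variant sets (VCF or TSV, e.g.
Mendelian / complex / cancer germline / cancer somatic) and want to
quantify, reproducibly:

* **Density** — how many unique disease variants each track holds per
  genomic region class, and the disease variants per million base pairs
  (DVPM = 10⁶ · n / L);
* **Background enrichment** — for each (category, track) pair, the 2×2
  within/outside odds ratio against a genome-variant background (the SNP
  panel minus all disease variants),

  OR = (DMW/DMO) / (DCW/DCO),

  with ln OR, its standard error
  SE = √(1/DMW + 1/DMO + 1/DCW + 1/DCO), and a Pearson chi-squared test
  (1 df, no continuity correction);
* **Matched-null enrichment** — the same odds ratio computed against N
  (default 1,000) equal-size control sets drawn from the background so
  that each matches the disease set's binned allele-frequency histogram
  *exactly*; summarized as the median replicate OR, the fraction of
  replicates significant at α, and a Benjamini–Hochberg q summary over
  the replicate p-values;
* **Annotation summaries** — severity-ranked consequence profiles
  (top-11-severe fraction over the 34-term Sequence Ontology ordering)
  and score-threshold fractions (e.g. Mutation Assessor ≥ 1.9,
  GERP > 0) over externally computed annotations.

A first-class synthetic-data module generates toy genomes, tracks,
background pools and disease sets with *planted* fold-enrichments
(placing variants in-track with probability λc/(λc + 1 − c) makes the
population odds ratio exactly λ), so the whole pipeline is testable
end-to-end with known ground truth.

## Worked example

Simulate a scenario with known truth, then run both enrichment analyses:

```r
library(regvar)

sc <- simulateScenario(syntheticConfig(seed = 1))

## background enrichment: every category against the pool-minus-disease
## background, here shown for the promoter track (planted lambdas:
## mendelian 20, cancer_somatic 10, cancer_germline 0 in this track,
## complex 0)
et <- enrichmentTable(sc$diseaseSets, sc$background, sc$tracks)
et[et$track == "promoter", c("category","track","dmw","dmo","odds_ratio","log_or","se","p")]
#>         category    track dmw  dmo odds_ratio   log_or      se          p
#>        mendelian promoter 333 1667    18.6059  2.92348 0.07420  0.000e+00
#>   cancer_somatic promoter 176 1824     8.9873  2.19581 0.09019 1.114e-188
#>  cancer_germline promoter   6  994     0.5622 -0.57586 0.41180  1.563e-01
#>          complex promoter  22 1978     1.0359  0.03532 0.21878  8.717e-01

## matched null: 200 allele-frequency-matched equal-size control sets
matchedEnrichment(sc$diseaseSets$mendelian, sc$background,
                  sc$tracks$promoter, nSets = 200, seed = 1)
#> MatchedNullResult mendelian ~ promoter: median OR 18.83 over 200
#> replicates (0 non-finite), q=9.5e-60, sig. fraction 1.000

## densities per track
dt <- densityTable(sc$diseaseSets, sc$tracks, sc$partition)
dt[, c("track","total_unique","track_length","dvpm_int")]
#>      track total_unique track_length dvpm_int
#>   promoter          537        30000    17900
#>   enhancer          156        60000     2600
#>  insulator          698       150000     4653
```

Reading the output: the set planted at 20-fold promoter enrichment comes
back with OR ≈ 18.6 against the raw background and a median matched-null
OR ≈ 18.8 (sampling noise around the planted 20); the set planted at
10-fold returns ≈ 9.0; the two sets not planted in promoters show OR ≈ 1
(the germline-cancer set's 0.56 has a wide SE — only 6 variants fall in
the track). DVPM values are large here because the toy disease sets are
dense relative to the 3-Mb toy genome; on real genome-scale inputs they
land in the tens-to-hundreds range.

File-based runs use the same functions behind a YAML config
(`readRunConfig()`, `runDensity()`, `runEnrichment()`,
`runMatchedNull()`, `runConsequences()`); a thin CLI wrapper lives at
`inst/scripts/regvar-pipeline.R`:

```sh
Rscript inst/scripts/regvar-pipeline.R simulate --seed 1 --out scenario/
Rscript inst/scripts/regvar-pipeline.R matched-null --config scenario/config.yaml --n-sets 1000
```

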