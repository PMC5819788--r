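# karyokit

Quantitative karyotype analysis and chromosome-evolution modelling for
plant complements characterized by 5S/45S rDNA FISH, built around the
canary grass genus *Phalaris* (Poaceae) — a genus combining two basic
chromosome numbers (x = 6, 7), diploid and tetraploid cytotypes, and three
distinguishable genomes (A, B, C). The package is aimed at plant
cytogeneticists who want to go beyond descriptive karyotype tables: it
makes rearrangement hypotheses executable, genome assignments reproducible,
and character mapping on a phylogeny explicit.

## What it computes

For a somatic complement with chromosomes of long/short arm lengths
L_i, S_i (µm) and ploidy p:

* **TML** = Σ(L_i + S_i) / p — total monoploid length;
* **M_CA** = mean_i [(L_i − S_i)/(L_i + S_i)] × 100 — mean centromeric
  asymmetry (0 for all-metacentric complements);
* **CV_CL** = sd(L_i + S_i) / mean(L_i + S_i) × 100 — interchromosomal
  asymmetry;
* 45S/5S rDNA signal counts as *signals / bearing chromosomes*;
* Levan morphology classes from r = L/S (m ≤ 1.7 < sm ≤ 3 < st ≤ 7 < t).

On top of the data model sit four analysis layers:

1. a **rearrangement-event algebra** (pericentromeric fission,
   telomere-to-telomere fusion, pericentric/paracentric inversion,
   reciprocal translocation, auto-/allopolyploidy, rDNA gain/loss) with
   JSON scenario replay that conserves total chromatin length — the
   mechanism by which descending dysploidy (x = 7 → x = 6) changes
   chromosome number without changing DNA content;
2. a **genome-signature classifier** scoring diploid sub-complements
   against rule-encoded A/B/C signatures and inferring
   auto- vs allopolyploid origin;
3. **Fitch parsimony mapping** of karyotype characters on the genus tree;
4. a **synthetic-karyotype generator** with microscopy-style measurement
   noise, so every stage is testable without downloads.

Reconstructed karyotypes of the eight study species
(`phalaris_fixtures()`), hypothetical ancestral complements, and the six
evolution scenarios (`inst/extdata/scenarios/`) ship with the package.

## Worked example

```r
library(karyokit)
fx <- phalaris_fixtures()

fx[["P. brachystachys"]]
#> Karyotype of P. brachystachys: 2n = 12 (ploidy 2, x = 6)
#>   rDNA sites: 2 x 45S, 4 x 5S
```

2n = 12 identifies the dysploid x = 6 cytotype; the two 45S signals mark
the nucleolus organizer pair, and the four 5S signals are the diagnostic
double band on the A2 pair. Its karyological parameters (`tml()`, `mca()`,
`cvcl()`) print `TML = 50.2 um, M_CA = 25.6, CV_CL = 17.5` — the high M_CA
reflecting the four subtelocentric chromosomes of genome A.

Replaying the packaged descending-dysploidy scenario on the hypothesized
all-metacentric x = 7 ancestor:

```r
res <- replay(proto_a_karyotype(), packaged_scenario("FIG4_DYSPLOIDY"))
res$karyotype
#> Karyotype of PROTO_A: 2n = 12 (ploidy 2, x = 6)
#>   rDNA sites: 2 x 45S, 4 x 5S
```

One fission, two fusions and an inversion turn 2n = 14 into 2n = 12 with
exactly four sm/st chromosomes and the 5S double band (4 signals on 2
chromosomes), at constant total chromatin length — the derived genome-A
pattern. Genome assignment of a tetraploid:

```r
assign_genomes(fx[["P. aquatica"]])
#> P. aquatica: genome formula B/C (ALLOPOLYPLOID)
#>  copy n_chromosomes label score
#>     1            14     B     1
#>     2            14     C     1
```

## Analysis workflow

The numbered scripts under `analysis/` run the full study pipeline from
the repository root and write their tables and idiograms under `results/`:

| script | what it does |
|---|---|
| `01_fixtures_and_stats.R` | karyotype table (TML, M_CA, CV_CL, rDNA counts) and SVG idiograms |
| `02_dysploidy_replay.R` | replays the x = 7 → x = 6 scenario, event log, conservation check |
| `03_polyploidy_and_genomes.R` | ploidy series, B+C amphidiploid bookkeeping, genome calls, 500-replicate noise robustness |
| `04_tree_mapping.R` | character matrix, Fitch changes, genome-distribution checks |

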