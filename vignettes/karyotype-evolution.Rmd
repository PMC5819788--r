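---
title: "Modelling karyotype evolution from rDNA FISH data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling karyotype evolution from rDNA FISH data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyokit)
```

## The problem

Canary grasses (*Phalaris*, Poaceae) combine two basic chromosome numbers
(x = 6 and x = 7) with diploid and tetraploid cytotypes, and the positions of
the 5S and 45S ribosomal DNA arrays — mapped by fluorescence in situ
hybridisation (FISH) — differ diagnostically between lineages. karyokit turns
that qualitative cytogenetic picture into an explicit, testable model: a
quantitative karyotype data structure, the standard asymmetry statistics, an
algebra of chromosome rearrangement events that can replay hypothesized
evolutionary scenarios, a rule-based classifier for the three genomes (A, B,
C) recognized in the genus, and parsimony mapping of the derived characters
on the species tree.

## The karyotype model

A karyotype is the full somatic complement: one record per chromosome
(homologues individually), each with long- and short-arm lengths in
micrometres, an optional satellite (secondary constriction, metadata only —
it contributes no length), a genome label, and an ordered list of rDNA
sites. Within-arm positions are fractions in [0, 1] from the centromere to
the telomere; no base-pair scale exists for these data. The qualitative
position vocabulary is made computable by fixed bins on that fraction:

| class                  | bin          |
|------------------------|--------------|
| `CENTROMERIC_PROXIMAL` | [0, 0.25)    |
| `INTERCALARY`          | [0.25, 0.75) |
| `SUBTELOMERIC`         | [0.75, 0.95) |
| `TELOMERIC`            | [0.95, 1]    |

The bin boundaries are package conventions — the literature uses only the
words. Centromere position classes follow the Levan arm-ratio intervals,
with boundaries closed on the lower class: metacentric (m) for r = L/S in
[1, 1.7], submetacentric (sm) in (1.7, 3], subtelocentric (st) in (3, 7],
telocentric (t) above (a zero short arm yields r = Inf, class t). Arms are
named by length at construction, so a chromosome built with swapped arms
normalizes to the identical object, sites included.

## Karyological statistics

For a balanced complement with ploidy p:

* **TML** (total monoploid length) = (sum of all somatic chromosome
  lengths) / p. For allotetraploids `tml_by_genome()` additionally reports
  one monoploid total per genome.
* **M_CA** (mean centromeric asymmetry) = mean over chromosomes of
  (L − S)/(L + S) × 100. The per-chromosome mean is the primary definition;
  the pooled set-total variant is available via `mca(k, "set-total")`.
* **CV_CL** (interchromosomal asymmetry) = sd(length)/mean(length) × 100.
  The sample standard deviation (n − 1) is the default; a population-SD
  switch exists. Note that only the population variant is exactly invariant
  under whole-genome duplication — the sample variant shifts by the
  degrees-of-freedom factor sqrt(m(n−1)/(mn−1)), about 2% when duplicating
  a 14-chromosome complement.

`count_rdna()` reports each family as signals / bearing chromosomes, the
form used in karyotype tables.

## The rearrangement algebra

Events map karyotypes to karyotypes and, by design, conserve total
chromatin length (dysploidy changes chromosome number, not DNA amount);
only explicit rDNA gain/loss events edit the site inventory.

* **Pericentromeric fission** breaks a chromosome at the centromere, which
  is modelled as lost with zero length; the two arms persist as acentric
  segments whose site positions are re-expressed from the former
  centromeric end. A paracentromeric offset parameter is accepted for
  forward compatibility but the break is currently placed exactly at the
  centromere, matching the whole-arm translocation products drawn in the
  source idiograms.
* **End-to-end fusion** joins a segment telomere-to-telomere onto a
  recipient arm, so the segment's former centromeric end becomes the new
  terminus and centromere–telomere polarity of the material is maintained.
* **Pericentric inversion** inverts the segment spanning the centromere
  between one breakpoint per arm. We implement the physically consistent
  semantics: the new side lengths are S − ds + dl and L − dl + ds, material
  proximal to the breakpoints changes sides (distance to the centromere
  preserved), distal material stays. A consequence worth stating: with
  both breakpoints at the telomeres the operation is observationally the
  identity — whole-chromosome inversion cannot change morphology. The sm/st
  morphology of the derived x = 6 chromosomes therefore comes from the
  fusion step itself (it roughly doubles one arm), and the shipped
  dysploidy scenario uses a *paracentric* inversion of the fused arm — as
  the original figure caption describes — to carry both 5S sites distal.
* **Paracentric inversion** mirrors site positions inside an interval of
  one arm (p → a + b − p); arm lengths are untouched and the operation is
  an involution.
* **Reciprocal translocation** exchanges terminal segments distal to one
  breakpoint per chromosome; sites travel with their segments.
* **Autopolyploidy** replicates the complement; **allopolyploid merge**
  unites two labelled complements with the same basic number, adding
  ploidies. **rDNA loss/gain** edit sites by a selector (label, genome,
  arm, position class, optional chromosome limit).

Scenarios are ordered event lists stored as JSON
(`inst/extdata/scenarios/`); `replay()` applies them deterministically,
tracks acentric segments in a pool (re-use is an error), logs every event,
and re-derives the basic number when the complement is balanced again. By
default events act on all homologues of the target label, since FISH
observations are somatic and the modelled events affect homologue pairs
symmetrically.

```{r}
res <- replay(proto_a_karyotype(), packaged_scenario("FIG4_DYSPLOIDY"))
res$karyotype
res$log[, c("kind", "n_before", "n_after", "len_before", "len_after")]
```

## Genome signatures and assignment

The three genomes are encoded as four equally weighted rule families per
signature — basic number, morphology composition, 45S pattern, 5S pattern —
evaluated on a *diploid* sub-complement (2x chromosomes), the unit in which
karyotype tables report "pairs":

* **A** (x = 6): at least four sm/st chromosomes; one pair of distal
  (subtelomeric/telomeric) 45S sites in the short arms; one pair of
  long-arm distal 5S double bands (two sites on one pair).
* **B** (x = 7): "more symmetrical", encoded as sub-complement M_CA < 20;
  one intercalary 45S pair (arm unconstrained — it varies among the B
  karyotypes); one (sub-)telomeric 5S pair.
* **C** (x = 7): M_CA < 20; one centromere-proximal short-arm 45S pair;
  5–6 pairs of 5S sites (positions unconstrained).

Signal-count rules tolerate one missing and one stray signal: counts are
accepted in [2·pairs − 1, 2·pairs] at the stated arm/position with at most
one off-pattern site. The rationale is physical — on a single metaphase
plate an individual FISH signal can fail to resolve, and a genome call
should not flip because one of two homologous signals dropped out. The
score is the satisfied fraction of the four rules; `assign_genomes()`
partitions the complement into diploid genome copies (by genome label and
homologue designation), takes the argmax signature per copy (ties broken
in A, B, C order), labels copies below 0.75 as UNKNOWN, and renders the
formula in table style: one letter per diploid genome copy ("A", "BB",
"B/C"). Ploidy type follows: DIPLOID at ploidy 2, AUTOPOLYPLOID above with
one distinct label, ALLOPOLYPLOID with several.

The 0.75 threshold and equal weights are deliberate artifact choices —
transparent and individually testable, unlike an opaque distance metric. A
copy matching three of four rule families (e.g. the 5S-free second B copy
of the *P. arundinacea* model, or *P. paradoxa* with its short-arm
intercalary 5S) still calls correctly at exactly 0.75.

## Fixtures are reconstructions

Per-chromosome arm lengths were never published for these accessions. The
packaged fixtures (`phalaris_fixtures()`) therefore reconstruct them
deterministically: chromosome lengths follow a symmetric linear series
scaled to reproduce the published TML exactly and the published CV_CL
approximately; arm ratios are hand-chosen lists approximating the published
M_CA and the m/sm/st composition of the idiograms. Signal counts, bearing
chromosomes, 2n, ploidy and genome composition match the publication
exactly; everything metric is a documented reconstruction. Specific
choices:

* *P. coerulescens* is built with M_CA ≈ 16.9. Its published main-row value
  (21.3) conflicts with the B-genome "more symmetrical" description and
  with the per-genome subrows (18.5/19.3) of the same table, which appear
  to suffer row-alignment typos; we keep the fixture safely inside the
  symmetric regime.
* *P. arundinacea*'s two 45S signals described as proximal next to the
  secondary constriction are placed at arm fraction 0.32 — just inside the
  intercalary bin. With one mid-arm and one proximal signal per genome
  copy, no single signal dropout can erase all intercalary 45S evidence
  from a copy.
* *P. minor*'s C copy carries no 45S (nucleolar dominance having removed
  the C-parent pair, the surviving pair sits on B1), and its C6 pair holds
  the subtelomeric 5S double site that brings the total to 16 signals on
  14 chromosomes.
* `PROTO_A` is the fictive all-metacentric x = 7 ancestor (TML 40 µm,
  within the range of the extant species); `ANCESTRAL_B` the
  coerulescens-like ancient B karyotype; `genome_template()` builds minimal
  signature-pure diploids used as merge parents.

## The synthetic generator and its noise model

`generate_karyotype()` emulates a grass karyotype of given x, ploidy, mean
chromosome length and interchromosomal CV (hit exactly before noise, via a
standardized normal spread), with arm ratios from a shifted log-normal and
rDNA pairs placed per plan, uniformly within their position-class bin.
Homologues are identical before noise. `perturb_karyotype()` then emulates
measurement: independent multiplicative log-normal noise per arm (default
CV 5%), independent per-signal dropout (default 2%), Gaussian position
jitter (default sd 0.03, clamped and re-binned), homologues perturbed
independently because each is a separate measurement. Defaults were chosen
once as plausible microscopy-scale variability.

What the generator does *not* emulate: chromatin condensation differences
between plates (which rescale all lengths jointly), correlated signal loss
(hybridisation failure affects whole plates), satellite/NOR extension, or
between-accession polymorphism. Passing the noise-robustness experiments
therefore demonstrates stability to per-measurement error, not to every
source of real-world variation.

## Parsimony mapping

The packaged eight-species topology is transcribed from the published
subgenus/section structure (the two x = 6 species of subgenus *Phalaris*
sister to subgenus *Phalaroides*; within the latter, the
*Phalaroides* + *Caroliniana* pair sister to *Heterachne* +
*Bulbophalaris*, with *P. coerulescens* outside *P. paradoxa* + the two
allotetraploids). Branch lengths are omitted. Characters are mapped with
unordered Fitch parsimony — the verbal directionality arguments provide no
cost model, so Dollo/ordered variants were not adopted; the per-node state
sets of the bottom-up pass are exposed, and one most-parsimonious
reconstruction is refined top-down to locate change edges (the state choice
at an ambiguous root is arbitrary, so downstream checks avoid asserting
direction at the root). The implementation is validated against an
exhaustive enumeration of internal labellings and against an independent
library parsimony score.

## Numerical conventions and degenerate inputs

Fractions are re-binned after every event; values clamped to [0, 1]. A
zero-length short arm is legal (telocentric); a zero-length chromosome is
not. Validation never throws — it returns a list of violations — while
constructors enforce only local invariants. Empty karyotypes are permitted
as merge identities and count as zero everywhere. TSV round-trips write
lengths at full precision and site fractions at six decimals; the format
mandates the dot decimal separator (the source table mixes decimal commas
and dots; the file format does not). All randomness is seed-parameterized;
identical seeds give byte-identical TSV and SVG output.

Problem sizes used by the test suite are the package's own choices: 1000
random complements for the statistics oracle, 1000 random events for the
conservation properties, 500 noisy replicates per species (seeded) for the
assignment robustness experiment, and exhaustive parsimony enumeration on
the 8-leaf tree.

## Known limitations

* Band-level nomenclature (ISCN), base-pair coordinates, centromere
  sequence models and meiotic behaviour are out of scope.
* The genome signatures are calibrated to this genus; the M_CA < 20
  symmetry encoding and the position bins would need re-fitting for other
  groups.
* Fission currently breaks exactly at the centromere; true paracentromeric
  breaks with a length-carrying centric remnant are not modelled.
* The fixtures' metric reconstructions make statistics beyond counts, 2n
  and TML illustrative rather than measured; CV_CL of the *P. minor*
  reconstruction (~21) undershoots its published 25.8 because the
  between-genome length contrast is only partially recoverable from the
  published totals.
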