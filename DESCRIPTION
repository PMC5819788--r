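Package: karyokit
Title: Karyotype Analysis and Chromosome Rearrangement Modelling for rDNA FISH Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative karyotype analysis of plant chromosome
    complements characterized by 5S and 45S rDNA fluorescence in situ
    hybridisation. Provides a chromosome/karyotype data model with rDNA site
    annotations, the standard karyological asymmetry statistics (total
    monoploid length, mean centromeric asymmetry, interchromosomal asymmetry),
    an algebra of chromosome rearrangement events (pericentromeric fission,
    telomere-to-telomere fusion, inversions, reciprocal translocation, auto-
    and allopolyploidization, rDNA locus gain/loss) with scenario replay,
    rule-based genome signature classification with auto/allopolyploidy
    inference, Fitch small parsimony mapping of karyotype characters on a
    species tree, and a seeded synthetic karyotype generator with microscopy-
    style measurement noise. Ships reconstructed karyotypes of eight canary
    grass (Phalaris) species as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
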