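{
  "name": "P_AQUATICA",
  "apply_to_homologues": true,
  "note": "Origin of the P. aquatica allotetraploid by amphidiploid merger of a genome-B diploid (replay input, GENOME_B_TEMPLATE) with a genome-C diploid: both parental rDNA complements are retained (four 45S signals on four chromosomes, twelve 5S signals).",
  "events": [
    { "kind": "allopolyploid_merge", "partner": "GENOME_C_TEMPLATE", "species": "P. aquatica (modelled)" }
  ]
}
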