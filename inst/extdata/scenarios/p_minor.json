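{
  "name": "P_MINOR",
  "apply_to_homologues": true,
  "note": "Origin of the P. minor allotetraploid: amphidiploid merger of genome-B and genome-C diploids (replay on GENOME_B_TEMPLATE) followed by nucleolar dominance, modelled as loss of the 45S locus pair inherited from the C-genome progenitor; two 45S signals on two chromosomes remain.",
  "events": [
    { "kind": "allopolyploid_merge", "partner": "GENOME_C_TEMPLATE", "species": "P. minor (modelled)" },
    { "kind": "rdna_loss", "family": "45S", "genome": "C" }
  ]
}
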