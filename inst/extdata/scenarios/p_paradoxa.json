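{
  "name": "P_PARADOXA",
  "apply_to_homologues": true,
  "note": "Derivation of the P. paradoxa karyotype from the ancestral genome-B complement (replay on ANCESTRAL_B): loss of the 5S locus pair on B3, then a pericentric inversion of the 5S-bearing B2 pair that relocates the remaining 5S pair into the short arms (intercalary).",
  "events": [
    { "kind": "rdna_loss", "family": "5S", "label": "B3" },
    { "kind": "pericentric_inversion", "label": "B2", "frac_short": 0.9, "frac_long": 0.7 }
  ]
}
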