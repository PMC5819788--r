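{
  "name": "P_ARUNDINACEA",
  "apply_to_homologues": true,
  "note": "Origin of the P. arundinacea tetraploid by autopolyploidy of a genome-B diploid (replay on GENOME_B_TEMPLATE), followed by pericentric inversions in B1 and B2 (breakpoints illustrative; the observed rearrangement is not breakpoint-resolved) and loss of one 5S pair on B2, leaving two 5S signals per tetraploid complement.",
  "events": [
    { "kind": "autopolyploidy", "factor": 2 },
    { "kind": "pericentric_inversion", "label": "B1", "frac_short": 1.0, "frac_long": 0.8 },
    { "kind": "pericentric_inversion", "label": "B2", "frac_short": 0.3, "frac_long": 0.9 },
    { "kind": "rdna_loss", "family": "5S", "label": "B2", "limit": 2 }
  ]
}
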