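{
  "name": "FIG4_DYSPLOIDY",
  "apply_to_homologues": true,
  "note": "Descending dysploidy x=7 -> x=6 in the genome-A lineage: pericentromeric break of the proximal-5S chromosome proto-A7 with loss of its centromere, telomere-to-telomere fusion of the two arms onto the long arms of proto-A2 (which receives the 5S material) and proto-A6, then paracentric inversion within the fused A2 arm bringing both 5S sites distal. Produces a 2n=12 complement with four sm/st chromosomes and a 5S double band on the A2 pair.",
  "events": [
    { "kind": "fission_pericentromeric", "label": "A7" },
    { "kind": "end_to_end_fusion", "origin": "A7", "part": "long", "recipient": "A2", "recipient_arm": "LONG" },
    { "kind": "end_to_end_fusion", "origin": "A7", "part": "short", "recipient": "A6", "recipient_arm": "LONG" },
    { "kind": "paracentric_inversion", "label": "A2", "arm": "LONG", "frac_a": 0.30, "frac_b": 0.86 }
  ]
}
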