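{
  "name": "HYBRID_ARUN_X_AQUA",
  "apply_to_homologues": true,
  "note": "The octoploid hybrid between the two tetraploids: merge of the P. arundinacea complement (replay input) with the P. aquatica complement, giving 2n = 8x = 56.",
  "events": [
    { "kind": "allopolyploid_merge", "partner": "P. aquatica", "species": "P. arundinacea x P. aquatica" }
  ]
}
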