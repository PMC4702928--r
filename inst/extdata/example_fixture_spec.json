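[
 {"id": "ex1", "dna_sequence": "GCGCAATTGCGC",
  "probes": [{"kind": "helix", "target": "MajorGroove", "interaction": "hbond"},
             {"kind": "loop", "target": "Backbone", "interaction": "hbond"}]},
 {"id": "ex2", "dna_sequence": "GCGCAATTGCGC",
  "probes": [{"kind": "strand", "target": "Backbone", "interaction": "hydrophobic"}]}
]
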