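{
  "seed": 42,
  "synthio": {
    "n_tx": 150,
    "n_codons": 150,
    "n_clones": 2,
    "n_reps": 2,
    "depth": 500000,
    "dispersion": 0.1,
    "effect_aa": "L",
    "effect_offset": 31,
    "effect_factor": 2.5,
    "frame_noise": 0.1
  },
  "footprints": { "min_reads": 200 },
  "dwelltime": { "offsets": [20, 45] },
  "teglm": { "alpha": 0.01 }
}
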