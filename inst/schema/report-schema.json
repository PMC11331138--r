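{
  "title": "pocketmap pipeline report",
  "required": ["package", "version", "config", "candidates", "clusters",
               "clade", "rcm", "pockets", "enrichment"],
  "stages": {
    "candidates": ["n", "ids"],
    "clusters": ["n_records", "n_clusters"],
    "clade": ["n_tips", "tips"],
    "rcm": ["n_rep", "n_pos", "regional", "raw"],
    "pockets": ["calls"],
    "enrichment": ["observed", "p_value", "n_perm", "n_cells", "seed"]
  }
}
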