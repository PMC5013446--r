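{
  "n_nodes": 1141,
  "n_edges": 11688,
  "avg_path_length": 2.978,
  "diameter": 7,
  "clustering_coefficient": 0.2,
  "avg_degree": 20.031,
  "density": 0.017,
  "modularity": 0.452
}
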