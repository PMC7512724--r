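{
  "format": "bnpool-panel",
  "version": 1,
  "structure": {"name": "chain", "nodes": [{"name": "A", "states": ["t", "f"]}, {"name": "B", "states": ["t", "f"]}], "parents": {"A": [], "B": ["A"]}},
  "experts": [{"id": "x1", "cpts": {"A": [[0.80000000000000004, 0.19999999999999996]], "B": [[0.90000000000000002, 0.099999999999999978], [0.20000000000000001, 0.80000000000000004]]}}, {"id": "x2", "cpts": {"A": [[0.20000000000000001, 0.80000000000000004]], "B": [[0.59999999999999998, 0.40000000000000002], [0.29999999999999999, 0.69999999999999996]]}}],
  "covariates": [{"expert_id": "x1"}, {"expert_id": "x2"}],
  "weights": {"x1": 0.5, "x2": 0.5}
}
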