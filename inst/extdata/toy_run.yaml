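# run configuration for the bundled toy model (see the fluxnlp CLI)
network: toy_network.txt
model_config: toy_config.yaml
exchange_ub: 5
framework: cumomer
fragments:
  - {id: B12,  met: B, atoms: "1,2"}
  - {id: B23,  met: B, atoms: "2,3"}
  - {id: B123, met: B, atoms: "1,2,3"}
simulate:
  fluxes: {v0: 1.0, v1.f: 0.55, v1.b: 0.3, v2: 0.25, v3: 0.3, v4: 0.3, v5: 0.45, v6: 0.45, v7: 1.0}
  pools: {A: 1.5, B: 4.0, C: 2.0, D: 0.5, E: 0.8, F: 0.6}
  times: [2, 4, 6, 8, 10, 12, 14, 16, 18, 20]
  noise_sd: 0.01
  dt: 0.02
collocation:
  order: 3
  nodes: [0, 1, 2, 4, 6, 9, 12, 16, 20]
estimation:
  n_restarts: 5
  refine: true
  refine_order: 9
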