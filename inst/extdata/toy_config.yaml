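fixed:
  v0: 1.0
bounds:
  v1:
    lb: -5.0
    ub: 5.0
  v2:
    ub: 5.0
  v3:
    ub: 5.0
  v4:
    ub: 5.0
  v5:
    ub: 5.0
  v6:
    ub: 5.0
  v7:
    ub: 5.0
pools:
  A:
    lb: 0.05
    ub: 20.0
  B:
    lb: 0.05
    ub: 20.0
  C:
    lb: 0.05
    ub: 20.0
  D:
    lb: 0.05
    ub: 20.0
  E:
    lb: 0.05
    ub: 20.0
  F:
    lb: 0.05
    ub: 20.0
tracers:
- substrate: A.ext
  fraction: 1.0
  positions: U
  enrichment: 1.0
nat_abundance: 0.0
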