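# Synthetic three-pathway network: substrate A converted to product B via an
# intact reversible route (C), and two cleavage/recombination routes through
# the one-carbon pool D and the two-carbon units E and F.
v0: A.ext (abc) -> A (abc)
v1: A (abc) <-> C (abc)
v2: C (abc) -> B (abc)
v3: A (abc) -> D (a) + E (bc)
v4: D (a) + E (bc) -> B (abc)
v5: A (abc) -> F (ab) + D (c)
v6: F (ab) + D (c) -> B (abc)
v7: B (abc) -> B.ext (abc)
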