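# Tail-less nucleosome profile: all histone residues count as core; tail
# selections are rejected as not applicable.
name: tailless
dna_chains: [I, J]
chain_map:
  chain: [A, B, C, D, E, F, G, H]
  histone: [H3, H4, H2A, H2B, H3, H4, H2A, H2B]
  side: [3p, 3p, 3p, 3p, 5p, 5p, 5p, 5p]
tails: {}
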