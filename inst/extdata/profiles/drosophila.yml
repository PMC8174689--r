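# Drosophila-histone nucleosome profile (chain convention as in human.yml).
name: drosophila
dna_chains: [I, J]
chain_map:
  chain: [A, B, C, D, E, F, G, H]
  histone: [H3, H4, H2A, H2B, H3, H4, H2A, H2B]
  side: [3p, 3p, 3p, 3p, 5p, 5p, 5p, 5p]
tails:
  H3:
    - {terminus: N, from: 1, to: 45}
  H4:
    - {terminus: N, from: 1, to: 32}
  H2A:
    - {terminus: N, from: 1, to: 17}
    - {terminus: C, from: 115, to: 124}
  H2B:
    - {terminus: N, from: 1, to: 31}
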