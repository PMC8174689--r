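# Human-histone nucleosome profile. Chain naming follows the 1KX5-style
# convention: DNA strands I (sense) and J (antisense); histone chains A-H.
# Sides assign each histone copy to the nucleosome face nearer the 3' or 5'
# linker arm; adjust chain_map for structures using other conventions.
#
# H2A C-tail: the published core-exclusion list reads "1-18 and 129"; this
# profile interprets the C-terminal tail as residues 119-129. The range is
# configurable, not asserted.
name: human
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
    - {terminus: N, from: 1, to: 18}
    - {terminus: C, from: 119, to: 129}
  H2B:
    - {terminus: N, from: 1, to: 33}
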