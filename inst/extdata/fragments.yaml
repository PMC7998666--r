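# Fragment definitions for the 2-phenylquinoxaline + lithium phenylacetylide
# system, as accepted by read_fragments_yaml() and the --fragments CLI flag.
# Ranges run over serial numbers regardless of element ("N1-H15" spans the
# 15 quinoxaline-core atoms). Quote single-letter names YAML would read as
# booleans ("N", "Y").
fragments:
  Q: N1-H15
  Ph1: C16-H26
  Bn: C5-C10,H12-H15
  P: N1,C2,C3,N4,C5,C10,H11
  "N": N1,N4
  "C": C2,C3,C5,C10
  L: Li27,C28,C29
  A: C28,C29
  R: C28-H40
  Ph2: C30-H40
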