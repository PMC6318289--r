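# Example epitope definitions for `crispredits consequence --epitopes`.
# Spans are 1-based inclusive residue intervals on the wildtype protein.
# Y188 is a C-terminal APP antibody recognising the last 20 residues of
# the 695-residue isoform; loss of its epitope reports successful
# C-terminal truncation.
- name: Y188
  start: 676
  end: 695
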