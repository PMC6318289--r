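# Example simulation config for `crispredits simulate`.
# `reference` may be supplied inline here or via --reference FASTA.
cut_site: 177
editing_rate: 0.5
n_alleles: 5
del_prob: 0.7
size_geom_p: 0.5
max_offset: 5
error_rate: 0.002
depth: 20000
seed: 1
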