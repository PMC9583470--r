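# Example flat configuration for `dwispan generate`
# (command-line flags override these values)
n: 100
seed: 7
empty_fraction: 0
mean_dwi: 2
mean_other: 8
target_mean_length: 170
max_length: 525
shared_part_rate: 0.3
broken_writing_rate: 0.05
language_pack: romanized
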