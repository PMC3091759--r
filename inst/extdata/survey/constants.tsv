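# Survey-wide constants.
key	value
genome_mb	454
gc_pct	35.2
n_unigenes	23762
n_nonredundant	33372
n_bes	47140
n_paired_bes	43224
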