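# Reference tiered EST-homology hit counts at the double E-value cutoff.
tier	low_hits	high_hits
melon	7929	5072
other_cucurbit	3064	1478
non_cucurbit	379	80
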