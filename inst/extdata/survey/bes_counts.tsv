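# Reference BES read-set statistics per library and combined.
set	n_bes	n_paired	n_nonpaired	len_min	len_max	len_mean	total_mb
BCM	23878	21742	2136	50	879	552	13.2
RCM	23262	21482	1780	50	874	534	12.4
ALL	47140	43224	3916	50	879	543	25.6
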