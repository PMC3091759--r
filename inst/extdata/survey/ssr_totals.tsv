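# Reference microsatellite totals per sequence set.
set	n_ssrs	total_ssr_bp	total_sequence_bp
BCM	3034	54754	8900000
RCM	4264	77267	10500000
MERGED	7198	130222	18900000
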