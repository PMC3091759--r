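# Reference non-redundant sequence sets after per-library assembly and the
# joint cross-assembly (MERGED).
set	n_seq	n_contigs	n_singletons	total_mb
BCM	15408	4661	10747	8.9
RCM	19106	1488	17618	10.5
MERGED	33372	6411	26961	18.9
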