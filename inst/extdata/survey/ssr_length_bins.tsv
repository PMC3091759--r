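# Reference microsatellite length-bin counts (bins inclusive of lower bound).
bin_lo	bin_hi	bcm	rcm	merged
12	20	2404	3436	5759
21	50	576	748	1307
51	100	51	65	114
101	NA	3	15	18
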