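# Reference microsatellite counts per canonical motif class.
unit	motif_class	bcm	rcm	merged
1	A	1192	1546	2700
1	C	47	110	155
2	AT	482	710	1184
2	AG	190	250	429
2	AC	59	69	128
2	CG	4	0	4
3	AAT	392	674	1050
3	AAG	217	332	546
3	ATC	47	39	85
3	AAC	31	38	68
3	AGG	36	37	72
3	other	69	90	150
4	AAAT	65	95	159
4	AAAG	35	42	75
4	AATT	20	21	39
4	ACAT	5	21	26
4	AAAC	9	9	17
4	other	18	19	37
5	AGCCG	22	62	84
5	AAAAG	21	26	47
5	AAAAT	13	10	22
5	AAAAC	6	6	12
5	AATTT	3	7	9
5	other	22	16	36
6	AAAAAG	9	6	15
6	AAAAAT	3	3	6
6	AAAGAG	2	1	3
6	AAATTC	0	2	2
6	other	15	23	38
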