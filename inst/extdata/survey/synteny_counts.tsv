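# Reference paired-BES comparative-mapping funnel counts per subject genome.
# n_pairs_total is the number of available BES pairs (paired reads / 2).
genome	n_subjects	subject_mb	bes_hits	pair_hits	pairs_same_subject	n_loci	pairs_in_window	pairs_collinear	n_pairs_total
arabidopsis	5	135	2958	135	86	111	15	11	21612
grapevine	19	487	4919	334	195	350	86	56	21612
soybean	20	975	4446	282	171	437	73	57	21612
medicago	8	241	3214	155	102	210	30	24	21612
poplar	19	370	4676	315	171	276	95	76	21612
cucumber	117	149	30818	10296	6475	31385	4945	4138	21612
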