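# Reference repeat-annotation counts over the TE taxonomy.
class	subclass	element	count
Retroelements	LINES	L1	30
Retroelements	LTR	Ty1/Copia	1250
Retroelements	LTR	Ty3/Gypsy	709
Retroelements	LTR	Unclassified	41
DNA_transposons	.	hobo-Activator	35
DNA_transposons	.	En-Spm	171
DNA_transposons	.	MuDR	102
DNA_transposons	.	Harbinger	5
DNA_transposons	.	Unclassified	22
Rolling_circles	.	Helitron	12
Telomere	.	Telomere-related	3
rRNA	.	Small_subunit	36
rRNA	.	Large_subunit	62
rRNA	.	45S_ITS	7
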