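# Repeat taxonomy: leaf labels and the case-insensitive regex (first match
# wins, row order) that maps screening-tool family/class labels onto them.
class	subclass	element	pattern	is_te
Retroelements	LINES	L1	\bL1\b|LINE/L1	TRUE
Retroelements	LTR	Ty1/Copia	copia	TRUE
Retroelements	LTR	Ty3/Gypsy	gypsy	TRUE
DNA_transposons	.	hobo-Activator	hobo|activator|\bhAT\b	TRUE
DNA_transposons	.	En-Spm	en-?spm|CACTA	TRUE
DNA_transposons	.	MuDR	mudr|mutator	TRUE
DNA_transposons	.	Harbinger	harbinger|\bPIF\b	TRUE
Rolling_circles	.	Helitron	helitron	TRUE
Telomere	.	Telomere-related	telomer	FALSE
rRNA	.	45S_ITS	45S|ITS|internal.spacer	FALSE
rRNA	.	Small_subunit	SSU|18S|small.subunit	FALSE
rRNA	.	Large_subunit	LSU|25S|28S|large.subunit	FALSE
Retroelements	LINES	Unclassified	LINE	TRUE
Retroelements	LTR	Unclassified	LTR	TRUE
DNA_transposons	.	Unclassified	^DNA|DNA/	TRUE
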