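# Published reference counts from a melon BAC-end sequencing survey:
# the two BAC libraries (restriction-digest BCM, random-shear RCM).
library	vector	method	n_clones	true_fraction	true_clones	insert_kb	genome_mb
BCM	pECBAC1	restriction	23040	0.80	18432	139	454
RCM	pSMART	random_shear	30720	0.77	23655	120	454
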