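set	mirna	pos_hits	neg_hits
caste	Zne-mir-34-3p	55	0
caste	Zne-mir-263a-3p	24	0
caste	Zne-mir-6012-5p	267	16
caste	Zne-mir-2a-3-5p	10	0
caste	Zne-mir-125-5p	10	0
caste	Zne-mir-2796-3p	5	0
caste	Zne-mir-279c-5p	4	0
caste	Zne-mir-3049-5p	4	0
caste	Zne-mir-87-1-3p	14	4
caste	Zne-mir-981-5p	3	0
caste	all-miRNAs	556	136
sex	Zne-mir-34-3p	19	0
sex	Zne-mir-275-3p	9	0
sex	Zne-mir-998-5p	7	0
sex	Zne-mir-750-5p	6	0
sex	Zne-bantam-5p	14	4
sex	Zne-mir-6012-3p	3	0
sex	Zne-mir-278-5p	3	0
sex	Zne-mir-981-5p	2	0
sex	Zne-mir-279c-5p	2	0
sex	Zne-mir-184-5p	1	0
sex	all-miRNAs	222	110
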