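breed	locus	n_AA	n_Aa	n_aa
SmallTailHan	g.71874104G>A	42	167	166
Tan	g.71874104G>A	13	37	30
Sunite	g.71874104G>A	6	36	57
Suffolk	g.71874104G>A	4	13	21
Dorper	g.71874104G>A	5	9	14
PrairieTibetan	g.71874104G>A	13	48	69
SmallTailHan	g.71833755T>C	215	126	32
Tan	g.71833755T>C	51	22	7
Sunite	g.71833755T>C	69	21	6
Suffolk	g.71833755T>C	36	3	0
Dorper	g.71833755T>C	30	0	0
PrairieTibetan	g.71833755T>C	95	22	12
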