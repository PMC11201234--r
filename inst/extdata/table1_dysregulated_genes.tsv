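status	gene	chromosome	product	fold_change	change_coefficient
up	CALML5	10	Calcium-binding protein	7.09	86.48
up	S100A7	1	Enzyme inhibitor	7.85	84.86
up	KRT16	17	Cytokeratin	7.81	84.34
up	DEFB4A	8	Transporter	8.33	83.46
up	KRT6B	12	Cytokeratin	7.87	81.33
up	KRT14	17	Enzyme	7.37	80.98
up	DSG1	18	Enzyme	8.52	77.89
up	DEFB103A	8	Enzyme	10.24	76.14
up	CASP14	19	Enzyme	8.47	71.02
up	CRABP2	1	Transporter	6.44	68.69
down	C16orf82	16	Plasma protein	-125487.85	-444.63
down	PRB4	12	Cytoskeletal protein	-10386.22	-349.71
down	C11orf65	11	Cytoskeletal protein and plasma protein	-1174.07	-301.06
down	MTRNR2L8	11	Plasma protein	-1376.49	-255.23
down	DPEP1	16	Enzyme	-2730.08	-239.23
down	PRB3	12	Cysteine rich C-terminal 1	-1210.41	-237.90
down	NPAT	11	Plasma protein	-572.99	-224.71
down	MTRNR2L12	3	Cytoskeletal protein and plasma protein	-336.61	-186.51
down	ATM	11	Enzyme	-235.61	-153.15
down	CASP8	2	Cytoskeletal protein and plasma protein	-165.63	-152.26
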