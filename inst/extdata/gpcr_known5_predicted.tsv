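# Cascade-averaged hydropathy predictions (1-based inclusive) for the five
# GPCRs of known structure, as published: one prediction row-set per protein
# (for P28222 the n = 3 run, the one entering the published aggregate).
# The merged double domain of P41595 (89-151) is stored unsplit; the
# outer-boundary split recovers 89-109 and 131-151.
# Columns: protein_id, index, start, end, scale, n, level.
protein_id	index	start	end	scale	n	level
P47871	SP	11	23	H5	4	0.266
P47871	1	143	166	H5	4	0.266
P47871	2	180	192	H5	4	0.266
P47871	3	218	257	H5	4	0.266
P47871	4	261	288	H5	4	0.266
P47871	5	303	327	H5	4	0.266
P47871	6	353	368	H5	4	0.266
P47871	7	384	401	H5	4	0.266
P34998	SP	9	19	H3	5	-0.052
P34998	1	116	146	H3	5	-0.052
P34998	2	178	204	H3	5	-0.052
P34998	3	217	247	H3	5	-0.052
P34998	4	255	280	H3	5	-0.052
P34998	5	302	325	H3	5	-0.052
P34998	6	344	362	H3	5	-0.052
P34998	7	370	397	H3	5	-0.052
P07700	1	44	64	H3	4	0.1
P07700	2	81	99	H3	4	0.1
P07700	3	108	138	H3	4	0.1
P07700	4	160	181	H3	4	0.1
P07700	5	214	229	H3	4	0.1
P07700	6	293	314	H3	4	0.1
P07700	7	320	331	H3	4	0.1
P28222	1	45	73	H5	3	0.182
P28222	2	85	110	H5	3	0.182
P28222	3	118	145	H5	3	0.182
P28222	4	168	185	H5	3	0.182
P28222	5	205	229	H5	3	0.182
P28222	6	316	340	H5	3	0.182
P28222	7	344	370	H5	3	0.182
P41595	1	54	81	H5	5	0.164
P41595	2	89	151	H5	5	0.164
P41595	3	173	194	H5	5	0.164
P41595	4	215	243	H5	5	0.164
P41595	5	325	352	H5	5	0.164
P41595	6	356	381	H5	5	0.164
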