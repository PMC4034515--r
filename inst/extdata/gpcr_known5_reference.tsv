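# Reference TMD boundaries (UniProt-curated, 1-based inclusive) for the
# five GPCRs of known structure used in the benchmark evaluation.
# Columns: protein_id, index (TMD ordinal or SP), start, end.
protein_id	index	start	end
P47871	SP	1	25
P47871	1	137	161
P47871	2	174	198
P47871	3	226	249
P47871	4	264	285
P47871	5	304	326
P47871	6	351	369
P47871	7	382	402
P34998	SP	1	23
P34998	1	112	142
P34998	2	179	203
P34998	3	219	247
P34998	4	255	282
P34998	5	299	324
P34998	6	336	360
P34998	7	368	397
P07700	1	39	67
P07700	2	77	103
P07700	3	116	137
P07700	4	156	179
P07700	5	206	231
P07700	6	286	315
P07700	7	321	343
P28222	1	50	75
P28222	2	85	110
P28222	3	124	145
P28222	4	166	187
P28222	5	206	228
P28222	6	316	336
P28222	7	350	371
P41595	1	57	79
P41595	2	91	113
P41595	3	130	151
P41595	4	172	192
P41595	5	217	239
P41595	6	325	345
P41595	7	361	382
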