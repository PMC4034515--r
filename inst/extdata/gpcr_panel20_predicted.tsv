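# Cascade-averaged hydropathy predictions (1-based inclusive) for the
# 20-GPCR comparison panel, as published.  The merged double domain of
# P35414 (246-312, 6th+7th) is stored unsplit; the outer-boundary split
# recovers 246-266 and 292-312.
# Columns: protein_id, index, start, end, scale, n, level.
protein_id	index	start	end	scale	n	level
P21453	1	48	69	H5	5	0.25
P21453	2	83	107	H5	5	0.25
P21453	3	122	142	H5	5	0.25
P21453	4	160	195	H5	5	0.25
P21453	5	199	223	H5	5	0.25
P21453	6	255	281	H5	5	0.25
P21453	7	293	310	H5	5	0.25
P08172	1	21	48	H3	5	0.07
P08172	2	60	85	H3	5	0.07
P08172	3	90	122	H3	5	0.07
P08172	4	142	167	H3	5	0.07
P08172	5	192	208	H3	5	0.07
P08172	6	389	415	H3	5	0.07
P08172	7	422	429	H3	5	0.07
P08483	1	62	92	H5	5	0.30
P08483	2	105	128	H5	5	0.30
P08483	3	137	161	H5	5	0.30
P08483	4	187	208	H5	5	0.30
P08483	5	221	249	H5	5	0.30
P08483	6	492	515	H5	5	0.30
P08483	7	526	541	H5	5	0.30
P25024	1	39	67	H3	4	-0.05
P25024	2	76	96	H3	4	-0.05
P25024	3	102	141	H3	4	-0.05
P25024	4	152	175	H3	4	-0.05
P25024	5	199	230	H3	4	-0.05
P25024	6	241	267	H3	4	-0.05
P25024	7	291	308	H3	4	-0.05
P51681	1	33	56	H5	5	0.25
P51681	2	68	93	H5	5	0.25
P51681	3	100	136	H5	5	0.25
P51681	4	141	164	H5	5	0.25
P51681	5	196	218	H5	5	0.25
P51681	6	238	264	H5	5	0.25
P51681	7	288	299	H5	5	0.25
P35367	1	25	50	H5	5	0.17
P35367	2	63	93	H5	5	0.17
P35367	3	96	122	H5	5	0.17
P35367	4	147	167	H5	5	0.17
P35367	5	188	212	H5	5	0.17
P35367	6	418	442	H5	5	0.17
P35367	7	449	469	H5	5	0.17
P41145	1	56	83	H6	4	0.50
P41145	2	99	122	H6	4	0.50
P41145	3	143	151	H6	4	0.50
P41145	4	180	195	H6	4	0.50
P41145	5	227	248	H6	4	0.50
P41145	6	277	300	H6	4	0.50
P41145	7	302	320	H6	4	0.50
P42866	1	68	95	H3	4	-0.02
P42866	2	105	114	H3	4	-0.02
P42866	3	136	162	H3	4	-0.02
P42866	4	187	205	H3	4	-0.02
P42866	5	229	262	H3	4	-0.02
P42866	6	280	306	H3	4	-0.02
P42866	7	317	325	H3	4	-0.02
P32300	1	44	74	H5	5	0.213
P32300	2	85	102	H5	5	0.213
P32300	3	112	142	H5	5	0.213
P32300	4	167	187	H5	5	0.213
P32300	5	211	236	H5	5	0.213
P32300	6	263	286	H5	5	0.213
P32300	7	296	319	H5	5	0.213
P41146	1	42	79	H3	5	0.011
P41146	2	90	107	H3	5	0.011
P41146	3	112	130	H3	5	0.011
P41146	4	172	186	H3	5	0.011
P41146	5	212	241	H3	5	0.011
P41146	6	263	284	H3	5	0.011
P41146	7	301	335	H3	5	0.011
P20789	1	63	86	H5	5	0.144
P20789	2	103	139	H5	5	0.144
P20789	3	154	172	H5	5	0.144
P20789	4	191	208	H5	5	0.144
P20789	5	220	268	H5	5	0.144
P20789	6	306	324	H5	5	0.144
P20789	7	338	374	H5	5	0.144
P25116	SP	6	17	H3	4	0.100
P25116	1	101	133	H3	4	0.100
P25116	2	136	158	H3	4	0.100
P25116	3	175	208	H3	4	0.100
P25116	4	221	238	H3	4	0.100
P25116	5	270	296	H3	4	0.100
P25116	6	313	338	H3	4	0.100
P25116	7	350	371	H3	4	0.100
Q8TCB6	1	12	49	H5	5	0.300
Q8TCB6	2	60	77	H5	5	0.300
Q8TCB6	3	80	120	H5	5	0.300
Q8TCB6	4	146	166	H5	5	0.300
Q8TCB6	5	198	227	H5	5	0.300
Q8TCB6	6	243	260	H5	5	0.300
Q8TCB6	7	276	292	H5	5	0.300
Q99835	SP	13	23	H3	5	0.00
Q99835	1	236	251	H3	5	0.00
Q99835	2	264	283	H3	5	0.00
Q99835	3	313	340	H3	5	0.00
Q99835	4	362	380	H3	5	0.00
Q99835	5	403	425	H3	5	0.00
Q99835	6	451	473	H3	5	0.00
Q99835	7	519	545	H3	5	0.00
Q9UJ42	1	26	40	H5	5	0.420
Q9UJ42	2	59	81	H5	5	0.420
Q9UJ42	3	97	118	H5	5	0.420
Q9UJ42	4	139	157	H5	5	0.420
Q9UJ42	5	182	202	H5	5	0.420
Q9UJ42	6	244	271	H5	5	0.420
Q9UJ42	7	274	292	H5	5	0.420
Q9Y5N1	1	33	61	H3	5	0.00
Q9Y5N1	2	72	95	H3	5	0.00
Q9Y5N1	3	105	132	H3	5	0.00
Q9Y5N1	4	155	173	H3	5	0.00
Q9Y5N1	5	191	222	H3	5	0.00
Q9Y5N1	6	360	388	H3	5	0.00
Q9Y5N1	7	395	416	H3	5	0.00
Q9H3N8	1	16	41	H5	5	0.25
Q9H3N8	2	55	79	H5	5	0.25
Q9H3N8	3	83	107	H5	5	0.25
Q9H3N8	4	130	153	H5	5	0.25
Q9H3N8	5	169	198	H5	5	0.25
Q9H3N8	6	305	331	H5	5	0.25
Q9H3N8	7	341	357	H5	5	0.25
Q8NFJ5	1	26	53	H5	4	0.195
Q8NFJ5	2	68	92	H5	4	0.195
Q8NFJ5	3	96	118	H5	4	0.195
Q8NFJ5	4	130	155	H5	4	0.195
Q8NFJ5	5	178	202	H5	4	0.195
Q8NFJ5	6	213	233	H5	4	0.195
Q8NFJ5	7	246	265	H5	4	0.195
Q9GZP7	1	53	77	H4	5	0.754
Q9GZP7	2	90	103	H4	5	0.754
Q9GZP7	3	122	145	H4	5	0.754
Q9GZP7	4	165	188	H4	5	0.754
Q9GZP7	5	222	245	H4	5	0.754
Q9GZP7	6	274	301	H4	5	0.754
Q9GZP7	7	306	338	H4	5	0.754
P35414	1	30	52	H3	5	-0.090
P35414	2	67	85	H3	5	-0.090
P35414	3	98	135	H3	5	-0.090
P35414	4	147	167	H3	5	-0.090
P35414	5	208	228	H3	5	-0.090
P35414	6	246	312	H3	5	-0.090
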