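# Reference TMD boundaries (UniProt-annotated, 1-based inclusive) for the
# 20-GPCR comparison panel.  Columns: protein_id, index (TMD ordinal or SP),
# start, end.
protein_id	index	start	end
P21453	1	47	71
P21453	2	79	107
P21453	3	122	140
P21453	4	160	185
P21453	5	202	222
P21453	6	256	277
P21453	7	294	314
P08172	1	23	45
P08172	2	60	80
P08172	3	98	119
P08172	4	140	162
P08172	5	185	207
P08172	6	389	409
P08172	7	424	443
P08483	1	67	90
P08483	2	104	124
P08483	3	142	163
P08483	4	184	206
P08483	5	229	251
P08483	6	492	512
P08483	7	527	546
P25024	1	40	66
P25024	2	76	96
P25024	3	112	133
P25024	4	155	174
P25024	5	200	220
P25024	6	243	264
P25024	7	286	308
P51681	1	31	58
P51681	2	69	89
P51681	3	103	124
P51681	4	142	166
P51681	5	199	218
P51681	6	236	260
P51681	7	278	301
P35367	1	30	49
P35367	2	64	83
P35367	3	102	123
P35367	4	146	165
P35367	5	190	210
P35367	6	419	438
P35367	7	451	470
P41145	1	59	85
P41145	2	96	117
P41145	3	133	154
P41145	4	174	196
P41145	5	223	247
P41145	6	276	299
P41145	7	312	333
P42866	1	65	94
P42866	2	104	121
P42866	3	144	163
P42866	4	194	209
P42866	5	235	257
P42866	6	281	303
P42866	7	312	328
P32300	1	46	75
P32300	2	85	102
P32300	3	125	144
P32300	4	175	190
P32300	5	216	238
P32300	6	262	284
P32300	7	294	310
P41146	1	51	77
P41146	2	88	109
P41146	3	125	146
P41146	4	166	188
P41146	5	212	236
P41146	6	265	288
P41146	7	301	322
P20789	1	65	87
P20789	2	97	121
P20789	3	144	165
P20789	4	189	210
P20789	5	236	260
P20789	6	309	330
P20789	7	349	372
P25116	SP	1	21
P25116	1	103	128
P25116	2	138	157
P25116	3	177	198
P25116	4	219	239
P25116	5	269	288
P25116	6	312	334
P25116	7	351	374
Q8TCB6	1	28	48
Q8TCB6	2	57	77
Q8TCB6	3	102	122
Q8TCB6	4	142	162
Q8TCB6	5	199	219
Q8TCB6	6	239	259
Q8TCB6	7	275	295
Q99835	SP	1	27
Q99835	1	234	254
Q99835	2	263	283
Q99835	3	315	335
Q99835	4	359	379
Q99835	5	403	423
Q99835	6	452	472
Q99835	7	525	545
Q9UJ42	1	24	44
Q9UJ42	2	59	79
Q9UJ42	3	94	114
Q9UJ42	4	137	157
Q9UJ42	5	178	198
Q9UJ42	6	245	265
Q9UJ42	7	269	289
Q9Y5N1	1	40	60
Q9Y5N1	2	71	91
Q9Y5N1	3	109	129
Q9Y5N1	4	157	177
Q9Y5N1	5	197	217
Q9Y5N1	6	360	380
Q9Y5N1	7	396	416
Q9H3N8	1	20	40
Q9H3N8	2	53	73
Q9H3N8	3	88	108
Q9H3N8	4	132	152
Q9H3N8	5	173	193
Q9H3N8	6	305	325
Q9H3N8	7	342	362
Q8NFJ5	1	34	54
Q8NFJ5	2	69	89
Q8NFJ5	3	98	118
Q8NFJ5	4	130	150
Q8NFJ5	5	177	197
Q8NFJ5	6	213	233
Q8NFJ5	7	248	268
Q9GZP7	1	57	77
Q9GZP7	2	85	105
Q9GZP7	3	133	153
Q9GZP7	4	170	190
Q9GZP7	5	227	247
Q9GZP7	6	275	295
Q9GZP7	7	304	324
P35414	1	27	51
P35414	2	67	91
P35414	3	101	125
P35414	4	145	166
P35414	5	201	221
P35414	6	245	271
P35414	7	285	308
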