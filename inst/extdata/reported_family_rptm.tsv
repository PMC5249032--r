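family_id	control_1_rptm	control_2_rptm	ws_1_rptm	ws_2_rptm	reported_logfc
MIR5037	70	57	0	0	-9.0
MIR2119	4192	4134	157	133	-4.9
MIR5559	562	434	27	30	-4.1
MIR4408	45	38	7	5	-2.8
MIR1536	60	75	14	15	-2.2
MIR403	104	108	34	30	-1.7
MIR171	3938	3884	1138	1335	-1.7
MIR398	50	57	20	15	-1.6
MIR530	403	434	184	163	-1.3
MIR5370	94	99	34	49	-1.2
MIR4397-3	139	104	41	74	-1.1
MIR4391	462	443	259	177	-1.1
MIR3522	10815	10535	24937	26151	1.2
MIR408	219	264	504	719	1.3
MIR4344	15	19	55	44	1.5
MIR1535	30	14	68	79	1.7
MIR4411	25	14	82	49	1.7
MIR167	1357	1574	5426	5396	1.9
MIR4385	10	14	48	44	1.9
MIR397	254	174	961	917	2.1
MIR2111	104	80	382	488	2.2
MIR1512	209	207	1459	1281	2.7
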