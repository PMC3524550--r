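pathway	size	n_mitg	n_genes	n_mirnas	n_predictions	n_predictions_score
Cation transmembrane transporter activity	211	109	32	49	87	5
Gated channel activity	121	55	20	41	56	5
Ion transmembrane transporter activity	275	128	36	49	100	6
Nervous system development	382	191	63	70	278	28
Acevedo liver cancer with H3K27ME3 up	295	109	42	76	173	26
Acevedo liver cancer with H3K9ME3 up	141	50	19	49	72	7
Bertucci medullary vs. ductal breast cancer DN	177	88	33	64	111	15
Dacosta UV response via ERCC3 TTD DN	76	50	24	56	105	26
Hamai apoptosis via trail up	334	176	41	68	159	9
Lindgren bladder cancer cluster 3 DN	223	98	32	57	117	17
Manalo hypoxia up	211	123	37	65	123	10
Martinez response to trabectedin	42	26	15	38	52	8
Riggi ewing sarcoma progenitor up	429	222	69	83	290	21
Siligan bound by ews FLT1 fusion	36	18	14	47	68	16
Vecchi gastric cancer early DN	394	161	47	69	169	10
Verhaak AML with NPM1 mutated DN	266	130	35	62	119	2
Wang SMARCE1 targets up	170	92	29	54	99	17
Onder CDH1 signaling via CTNNB1	85	45	13	37	47	11
Sabates colorectal adenoma DN	292	118	38	62	130	12
Synaptic transmission	172	77	26	61	126	8
Neurological system process	377	139	49	69	225	12
Ion channel activity	147	70	22	42	65	5
Substrate specific channel activity	154	74	22	42	65	5
Transmission of nerve impulse	187	83	28	61	128	8
Cytoskeleton	361	173	36	68	160	7
Neuroactive ligand receptor interaction	272	94	28	58	112	2
Retinol metabolism	64	19	12	11	19	3
Drug metabolism other enzymes	51	20	13	11	20	0
Hatada methylated in lung cancer up	367	161	41	67	120	22
Delys thyroid cancer dn	214	109	42	67	168	20
Horiuchi wtap targets up	323	147	48	73	213	23
Thum systolic heart failure dn	248	136	41	77	192	12
Iwanaga carcinogenesis by kras pten DN	445	161	39	65	133	28
Doane response to androgen dn	248	119	29	53	101	7
Foster inflammatory response LPS DN	486	219	43	73	169	22
Acevedo liver cancer with H3K27ME3 DN	226	73	20	51	102	18
Boylan multiple myeloma C D DN	328	100	23	54	83	8
Yauch hedgehog signaling Paracrine DN	385	104	30	60	123	8
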