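pathway	type	size	n_mitg	n_non_mitg	pct_mitg	set
Cation transmembrane transporter activity	GO	211	109	85	56.2	core
Gated channel activity	GO	121	55	59	48.2	core
Ion transmembrane transporter activity	GO	275	128	123	51.0	core
Nervous system development	GO	382	191	135	58.6	core
Acevedo liver cancer with H3K27ME3 up	Curated	295	109	105	50.9	core
Acevedo liver cancer with H3K9ME3 up	Curated	141	50	55	47.6	core
Bertucci medullary vs. ductal breast cancer dn	Curated	177	88	54	62.0	core
Dacosta UV response via ERCC3 TTD DN	Curated	76	50	19	72.5	core
Hamai apoptosis via trail up	Curated	334	176	134	56.8	core
Lindgren bladder cancer cluster 3 DN	Curated	223	98	86	53.3	core
Manalo hypoxia up	Curated	211	123	58	68.0	core
Martinez response to trabectedin	Curated	42	26	13	66.7	core
Riggi ewing sarcoma progenitor up	Curated	429	222	133	62.5	core
Siligan bound by EWS FLT fusion	Curated	36	18	16	52.9	core
Vecchi gastric cancer early DN	Curated	394	161	125	56.3	core
Verhaak AML with NPM1 mutated DN	Curated	266	130	93	58.3	core
Wang SMARCE1 targets up	Curated	170	92	52	63.9	core
Onder CDH1 signaling via CTNNB1	Curated	85	45	31	59.2	core
Sabates colorectal adenoma DN	Curated	292	118	112	51.3	core
Synaptic transmission	GO	172	77	81	48.7	weighted
Neurological system process	GO	377	139	202	40.8	weighted
Ion channel activity	GO	147	70	69	50.4	weighted
Substrate specific channel activity	GO	154	74	72	50.7	weighted
Transmission of nerve impulse	GO	187	83	90	48.0	weighted
Cytoskeleton	GO	361	173	150	53.6	weighted
Neuroactive ligand receptor interaction	KEGG	272	94	144	39.5	weighted
Retinol metabolism	KEGG	64	19	38	33.3	weighted
Drug metabolism other enzymes	KEGG	51	20	24	45.5	weighted
Hatada methylated in lung cancer up	Curated	367	161	144	52.8	weighted
Delys thyroid cancer DN	Curated	214	109	86	55.9	weighted
Horiuchi WTAP targets up	Curated	323	147	119	55.3	weighted
Thum systolic heart failure DN	Curated	248	136	61	69.0	weighted
Iwanaga carcinogenesis by KRAS Pten DN	Curated	445	161	119	57.5	weighted
Doane response to androgen DN	Curated	248	119	94	55.9	weighted
Foster inflammatory response LPS DN	Curated	486	219	122	64.2	weighted
Acevedo liver cancer with H3K27ME3 DN	Curated	226	73	87	45.6	weighted
Boylan multiple myeloma C D DN	Curated	328	100	113	46.9	weighted
Yauch hedgehog signaling paracrine DN	Curated	385	104	108	49.1	weighted
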