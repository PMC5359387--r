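cluster_id	description	n0	n1	n2	n3	n_genes	score
Cluster001	Testis	541	236	212	639	1628	1.58
Cluster005	Nervous system - general	5	12	14	113	144	2.63
Cluster006	Nervous system - astrocytes	11	8	17	96	132	2.50
Cluster014	Mitochondria	0	6	15	66	87	2.69
Cluster027	Nervous system - dorsal root ganglia	3	4	5	48	60	2.63
Cluster030	Nervous system - neurons	7	5	7	48	67	2.43
Cluster035	Nervous system - oligodendrocytes	7	4	6	33	50	2.30
Cluster037	Nervous system - cerebellum	12	0	4	29	45	2.11
Cluster042	Nervous system - nucleus accumbens, dorsal striatum	8	2	3	26	39	2.21
Cluster045	Nervous system - neurons	3	0	2	32	37	2.70
Cluster048	Neurons and lung	1	6	3	21	31	2.42
Cluster053	Nervous system - neurons	1	5	0	13	19	2.32
Cluster056	Nervous system - cerebellum, other	6	1	1	10	18	1.83
Cluster059	Nervous system - neurons	0	1	2	23	26	2.85
Cluster060	Nervous system - neurons	1	1	2	17	21	2.67
Cluster066	Nervous system - neurons, dorsal root ganglia	0	3	7	9	19	2.32
Cluster073	Nervous system - neurons	3	2	1	11	17	2.18
Cluster077	Nervous system - neurons	1	2	5	11	19	2.37
Cluster082	Olfactory bulb	3	1	1	13	18	2.33
Cluster085	Nervous system - microglia	1	1	1	18	21	2.71
Cluster088	Nervous system - dorsal root ganglia, other	4	3	0	5	12	1.50
Cluster089	Nervous system - neurons	3	1	2	12	18	2.28
Cluster090	Nervous system - spinal cord, adult brain	2	0	0	11	13	2.54
Cluster091	Nervous system - myelin synthesis	0	1	0	7	8	2.75
Cluster096	Nervous system - nucleus accumbens, dorsal striatum	2	3	1	8	14	2.07
Cluster099	Nervous system - neurons	1	0	4	8	13	2.46
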