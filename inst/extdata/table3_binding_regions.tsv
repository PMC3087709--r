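gene_ids	homologue_ids	product	fold_change_T30_glnR	sites
Sven_1863	SCO2198	GSI	-1.2	TTAACTTCGACGAAAC;GTCATGCTTGAGAAAT
Sven_1874	SCO2210	GSII	-291.6	GTAACACGGGGTTCAC;GCAACCGACGGGAAAT
Sven_7046	n/a	NRPS cluster	1.1	GAAACACGGGCGAAAC
Sven_5517	SCO5842	putative acetyltransferase	1.4	n/a
Sven_6731	SCO5931	xylanase	-1.5	GAAACATCTTCGAAAC
Sven_5279	SCO5583	AmtB	-624.7	GTCACGGCTCCGAAAC;TTCACGGTCGCGTAAC
Sven_4770	n/a	unknown	-1.1	TTAACGCGCAGGCAAC
Sven_3917/3918	SCO4159/4160	GlnR/putative hydrolase	(n/a)/30.7	TTCATCCATCCGTAAC
Sven_6152/6153	n/a	ATP-cassette/cytochrome P450	1.0/-1.2	GTTACCCCCACGTAAC;GTTACCGTCGGGTCAC;GTAACCGGTCGGTAAG;GTGACCCGACGGTAAC
Sven_6199/6200	n/a	NRPS cluster	1.7/3.2	TTCACTCCGGCGAAAC;GTGACCGCTGAGTAGC;TTGATCTCCTGGTAAA
Sven_2720	SCO2958	fused RR/uroporphrinogen III synthase	-13.7	n/a
Sven_2830	n/a	beta-glucan synthesis	-1.4	n/a
Sven_0629/0630	SCO6598/0545	LacI family repressor/secreted protein	2.5/1.5	GATACAGGGGGGAAAC
Sven_0867	SCO1293	N-acetyl glutamate synthase	-9.1	TTAACCCGTCAGTCAC
Sven_1634	SCO2008	branched chain amino acid binding protein	-1.3	ATAACAAGACAGTCAC
Sven_1677	SCO2026	glutamate synthase	-1.1	GTAACCTGCACGAAAT
Sven_5967	SCO3051	FadE acetyl CoA dehydrogenase	-1.3	GACACCCCGAGTTAAC
Sven_6632	SCO5685	putative sugar hydrolase	1.4	GTTAAGTGAACGTCAC
Sven_0035	-	secreted protein	-1.2	GTGACGCCGAGGTTAC
Sven_2895	SCO3092	fragment of NADH dehydrogenase	1	TTCACAAGGGGTGAAC
Sven_2285	SCO4892	transcriptional regulator	1.1	GAAACACCCTGGTAAC
Sven_6163	n/a	unknown	-1.6	n/a
Sven_2694	SCO2937	transcriptional regulator	-1.4	n/a
Sven_0835	SCO1236	UreA	-2.5	TTAACGAGCCGGAAAA
Sven_1338/1339	SCO1721/n/a	probable serine/threonine protein kinase	1.6/-1.4	GATACACGGGTGTCAC
Sven_1860	SCO2195	unknown	-4.5	GTCACGCCCTGGTAAC
Sven_6307	SCO6473	crotonyl-CoA reductase	-1.7	n/a
Sven_5972/5973	n/a	JadR2/JadR1	1.1/-1.7	TTAATGGCGGCGTCAC;TTGACCACTTCTTGAC;TTGACACGGAGTTGAC;GTCAACTCCGTGTCAA
Sven_0812	SCO2423	secreted protein	1.3	GTTTCCCGCAAGTAAC
Sven_1894/1895	SCO2231/2232	maltose binding protein/transcriptional repressor	1.1/1.2	GACACGCGGATGTAAC
Sven_3785	SCO4034	RNA polymerase sigma factor N	-1	n/a
Sven_4759	n/a	putative peptide transport system secreted peptide-binding protein	1.6	n/a
Sven_1354	SCO1735	probable secreted lipase	1.3	TTTACCGACGCGTAAC;GTCACGCCTTCATGAC
Sven_6299/6300	n/a/SCO6803	epimerase/acetyl transferase	1.9/-6.1	TTCACGTGCCCGAAAC
Sven_7354	SCO7012	putative binding protein dependent transport protein permease	-3.7	n/a
Sven_7089	n/a	assimilatory nitrate reductase	-1.8	GTGACACAGGTGTAAC
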