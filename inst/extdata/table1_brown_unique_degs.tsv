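stage	group_id	n_groups	description	gtr_rpkm	gtr_fc	ppl_rpkm	ppl_fc
early	MCL_5471	1	Hypothetical membrane protein	427.2	75.9	282.0	12.5
early	MCL_7627	1	SAM-dependent methyltransferase	958.5	57.4	44.3	9.2
early	MCL_3182	1	Membrane integrating ferric reductase	169.1	16.3	100.3	12.2
early	MCL_187	1	bZIP transcription factor	125.2	14.9	95.6	5.9
early	MCL_7588	1	Ribonuclease h-related	33.3	11.3	15.0	4.3
early	MCL_562	1	Zn(2)-C6 fungal transcription factor	74.3	9.4	60.5	28.3
early	MCL_1312	1	Hypothetical membrane protein	2182.6	8.6	233.5	4.9
early	MCL_4304	1	Receptor of activated protein kinase C	554.0	5.7	650.6	5.0
early	MCL_5286	1	SRP-dependent cotranslational protein	264.3	5.4	750.2	10.2
early	MCL_7002	1	Hypothetical membrane protein SignalP-TM	266.8	5.2	39.4	10.1
early	MCL_5385	1	Hyaluronan/mRNA-binding protein	677.0	5.1	357.2	4.8
early	RIBOSOMAL_19	19	Ribosomal structure	18084.9	4.9	16973.8	4.8
early	MCL_47	1	NmrA-like protein	26.2	4.9	60.2	10.2
early	MCL_1200	1	bZIP transcription factor	47.8	4.3	19.9	5.7
early	MCL_2183	1	Heme-thiolate peroxidase/peroxygenase	90.1	4.3	25.8	4.1
early	MCL_384	1	Hypothetical protein	186.1	4.1	233.3	4.2
late	MCL_7542	1	GH5, endo-beta-1,4-glucanase, SignalP-noTM	10613.2	24.1	12208.0	10.7
late	MCL_2441	1	GH3, beta-glucosidase, SignalP-noTM	3309.1	21.6	2982.9	5.0
late	MCL_2166	1	NAD(P)-binding oxidoreductase	765.7	8.6	963.4	5.3
late	MCL_4879	1	Aldo keto reductase	1298.5	7.9	945.9	5.6
late	MCL_2248	1	GH3, beta-glucosidase	487.1	7.7	639.3	6.5
late	MCL_5876	1	Uncharacterized UPF0261	37.2	6.9	138.8	9.2
late	MCL_6280	1	Uncharacterized UPF0303	678.8	6.9	1871.6	8.7
late	MCL_2280	1	Thioredoxin	1585.8	5.8	3622.7	5.9
late	MCL_7782	1	K(+) channel subunit/aldo keto reductase	4302.2	5.5	1197.9	10.6
late	MCL_3957	1	Malate synthase, glyoxysomal	1490.2	5.4	1028.4	5.1
late	MCL_3499	1	NADP-dependent 3-OH acid dehydrogenase	1014.0	5.0	1607.1	6.7
late	MCL_7264	1	Carboxyl esterase, SignalP-noTM	617.2	4.8	1459.4	8.0
late	MCL_6643	1	Sugar transporter	423.6	4.7	1065.4	4.1
late	MCL_1455	1	Malic enzyme	235.3	4.4	181.9	4.4
late	MCL_5447	1	Peptidyl-prolyl cis-trans isomerase	3444.1	4.3	4415.2	9.0
late	MCL_2204	1	Aldo keto reductase	2030.3	4.3	1376.7	7.9
late	MCL_3421	1	Aldo keto reductase	1140.9	4.1	538.6	5.1
late	MCL_2530	1	Glyoxalase/peptidase	130.7	4.0	599.1	4.5
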