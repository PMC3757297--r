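panel	feature	drug	leg	r	p	n
mRNA	BTG2_201236_s_at	Rapamycin	expr_auc	0.27	6.97e-6	272
mRNA	BTG2_201236_s_at	Everolimus	expr_auc	0.26	1.56e-5	272
mRNA	FBXW7_229419_at	Rapamycin	expr_auc	0.26	1.95e-5	272
mRNA	FBXW7_229419_at	Everolimus	expr_auc	0.30	3.88e-7	272
mRNA	STAU1_207320_x_at	Rapamycin	expr_auc	0.25	2.48e-5	272
mRNA	STAU1_207320_x_at	Everolimus	expr_auc	0.25	3.04e-5	272
mRNA	GIMAP7_228071_at	Rapamycin	expr_auc	-0.25	3.91e-5	272
mRNA	GIMAP7_228071_at	Everolimus	expr_auc	-0.25	3.80e-5	272
mRNA	PHLDA1_217996_at	Rapamycin	expr_auc	0.24	4.48e-5	272
mRNA	PHLDA1_217996_at	Everolimus	expr_auc	0.28	3.86e-6	272
mRNA	NDUFAF2_228355_s_at	Rapamycin	expr_auc	-0.24	4.75e-5	272
mRNA	NDUFAF2_228355_s_at	Everolimus	expr_auc	-0.25	2.17e-5	272
mRNA	SLC39A9_222445_at	Rapamycin	expr_auc	0.23	6.79e-5	272
mRNA	SLC39A9_222445_at	Everolimus	expr_auc	0.26	1.48e-5	272
mRNA	GIMAP1_1552316_a_at	Rapamycin	expr_auc	-0.24	8.16e-5	272
mRNA	GIMAP1_1552316_a_at	Everolimus	expr_auc	-0.27	5.48e-6	272
mRNA	ECOP_208091_s_at	Rapamycin	expr_auc	0.23	9.42e-5	272
mRNA	ECOP_208091_s_at	Everolimus	expr_auc	0.29	1.05e-6	272
mRNA	MGLL_225102_at	Rapamycin	expr_auc	0.23	1.04e-4	272
mRNA	MGLL_225102_at	Everolimus	expr_auc	0.25	3.94e-5	272
mRNA	PBX3_204082_at	Rapamycin	expr_auc	0.28	3.45e-6	272
mRNA	ZNF765_1558942_at	Rapamycin	expr_auc	0.24	6.84e-5	272
mRNA	ZNF765_1558943_x_at	Rapamycin	expr_auc	0.25	3.49e-5	272
mRNA	GIMAP6_229367_s_at	Everolimus	expr_auc	-0.2646	9.79e-6	272
SNP	rs17664713	Rapamycin	snp_auc	-0.28	4.70e-6	272
SNP	rs17664713	Everolimus	snp_auc	-0.27	1.60e-5	272
SNP	rs17732246	Rapamycin	snp_auc	-0.25	8.63e-5	272
SNP	rs17732246	Everolimus	snp_auc	-0.26	4.60e-5	272
SNP	rs11075286	Rapamycin	snp_auc	-0.26	3.93e-5	272
SNP	rs11075286	Everolimus	snp_auc	-0.25	6.30e-5	272
SNP	rs4148330	Rapamycin	snp_auc	-0.26	2.27e-5	272
SNP	rs4148330	Everolimus	snp_auc	-0.27	9.80e-6	272
SNP	rs2076523	Rapamycin	snp_auc	-0.26	2.77e-5	272
SNP	rs3809835	Rapamycin	snp_auc	-0.25	7.73e-5	272
SNP	rs10780752_222445_at	NA	snp_expr	-0.26	2.03e-5	272
SNP	rs10780752	Rapamycin	snp_auc	-0.25	4.90e-5	272
SNP	rs10780752	Everolimus	snp_auc	-0.26	3.49e-5	272
mRNA	SLC39A9_222445_at_panelC	Rapamycin	expr_auc	0.24	6.79e-5	272
mRNA	SLC39A9_222445_at_panelC	Everolimus	expr_auc	0.26	1.48e-5	272
SNP	rs7543260_203881_s_at	NA	snp_expr	-0.24	6.09e-5	272
SNP	rs7543260	Rapamycin	snp_auc	-0.24	9.78e-5	272
SNP	rs7543260	Everolimus	snp_auc	-0.26	2.35e-5	272
mRNA	DMD_203881_s_at	Rapamycin	expr_auc	0.20	9.54e-4	272
mRNA	DMD_203881_s_at	Everolimus	expr_auc	0.22	2.98e-4	272
SNP	rs10870177_218470_at	NA	snp_expr	0.24	5.26e-5	272
SNP	rs10870177	Rapamycin	snp_auc	-0.24	8.04e-5	272
SNP	rs10870177	Everolimus	snp_auc	-0.264	1.99e-5	272
mRNA	YARS2_218470_at	Rapamycin	expr_auc	-0.23	1.72e-4	272
mRNA	YARS2_218470_at	Everolimus	expr_auc	-0.24	5.87e-5	272
SNP	rs4144048_235790_at	NA	snp_expr	-0.24	6.37e-5	272
SNP	rs4144048	Rapamycin	snp_auc	0.25	6.20e-5	272
mRNA	LOC100131081_235790_at	Rapamycin	expr_auc	-0.21	3.55e-4	272
miRNA	miR-10a_ILMN_3167552	Everolimus	mirna_auc	0.2377	1.04e-4	262
miRNA	miR-10a_ILMN_3167552	Rapamycin	mirna_auc	0.2610	4.25e-4	262
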