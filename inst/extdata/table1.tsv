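block	feature	baseMean	log2fc
ASC_cells	hsa-let-7i-3p	479	-1.6
ASC_cells	hsa-miR-146b-5p	20821	2.1
ASC_cells	hsa-miR-1908-5p	39	1.5
ASC_cells	hsa-miR-210-3p	1191	-2.8
ASC_cells	hsa-miR-210-5p	89	-2.9
ASC_cells	hsa-miR-222-5p	151	-1.5
ASC_cells	hsa-miR-335-3p	1681	-4.0
ASC_cells	hsa-miR-335-5p	1248	-3.5
ASC_cells	hsa-miR-6842-3p	281	2.2
ASC_cells	hsa-miR-95-3p	172	6.2
BMSC_cells	hsa-let-7i-3p	427	-1.0
BMSC_cells	hsa-miR-146b-5p	3630	-1.1
BMSC_cells	hsa-miR-1908-5p	31	1.7
BMSC_cells	hsa-miR-210-3p	1236	-1.7
BMSC_cells	hsa-miR-210-5p	104	-1.5
BMSC_cells	hsa-miR-222-5p	443	1.0
BMSC_cells	hsa-miR-335-3p	3536	-2.6
BMSC_cells	hsa-miR-335-5p	2835	-1.7
BMSC_cells	hsa-miR-6842-3p	65	3.8
BMSC_cells	hsa-miR-95-3p	21	5.0
ASC_cells_vs_EV	hsa-miR-125b-2-3p	808	1.1
ASC_cells_vs_EV	hsa-miR-425-5p	1440	1.1
ASC_EVs	hsa-miR-425-5p	15	-4.8
ASC_EVs	hsa-miR-125b-2-3p	29	4.7
BMSC_cells_vs_EV	hsa-miR-133a-3p	120	1.3
BMSC_cells_vs_EV	hsa-miR-146a-5p	86	-1.1
BMSC_cells_vs_EV	hsa-miR-146b-5p	3630	-1.1
BMSC_cells_vs_EV	hsa-miR-155-5p	871	-1.4
BMSC_cells_vs_EV	hsa-miR-378a-3p	2747	-1.4
BMSC_cells_vs_EV	hsa-miR-483-5p	168	8.5
BMSC_EVs	hsa-miR-133a-3p	15	7.1
BMSC_EVs	hsa-miR-146a-5p	26	-3.9
BMSC_EVs	hsa-miR-146b-5p	1450	-2.2
BMSC_EVs	hsa-miR-155-5p	183	-1.1
BMSC_EVs	hsa-miR-378a-3p	1026	-1.9
BMSC_EVs	hsa-miR-483-5p	20	7.5
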