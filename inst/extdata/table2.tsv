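feature	baseMean	log2fc
hsa-miR-10b-5p	172238	-1.1
hsa-miR-10a-5p	71894	-2.0
hsa-miR-22-3p	44127	1.3
hsa-miR-191-5p	30963	-1.4
hsa-miR-486-5p	22431	-1.2
hsa-miR-100-5p	20117	-1.1
hsa-miR-146b-5p	1450	-2.2
hsa-miR-378a-3p	1026	-1.9
hsa-let-7d-5p	908	1.2
hsa-miR-30c-5p	370	1.3
hsa-miR-155-5p	183	-1.1
hsa-let-7d-3p	168	1.3
hsa-miR-12136	94	-2.3
hsa-miR-1910-5p	82	9.5
hsa-miR-4516	81	-3.0
hsa-miR-877-5p	42	2.0
hsa-miR-146a-5p	26	-3.9
hsa-miR-483-5p	20	7.5
hsa-miR-133a-3p	15	7.1
hsa-miR-3180-3p	14	-7.6
hsa-miR-34b-5p	10	6.5
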