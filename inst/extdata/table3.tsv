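feature	baseMean	log2fc
hsa-miR-769-5p	20	-3.7
hsa-miR-425-5p	15	-4.8
hsa-miR-125b-2-3p	29	4.7
hsa-miR-145-5p	97	-5.9
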