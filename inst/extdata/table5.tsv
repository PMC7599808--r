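block	feature	baseMean	log2fc	note
BMSC_EVs	Ser-ACT	15	5.4	fragment
BMSC_EVs	Ser-GCT	753	2.0	fragment
BMSC_EVs	Sup-TTA	35	3.9	fragment
BMSC_EVs	Phe-GAA	826	2.2	fragment
BMSC_EVs	Ile-AAT	545	2.8	fragment
BMSC_EVs	Lys-TTT	4439	1.4	fragment
BMSC_EVs	Gly-CCC	236570	-2.9	halve
BMSC_EVs	Leu-TAG	393	1.9	fragment
BMSC_EVs	Gly-GCC	804325	-2.8	halve
BMSC_EVs	His-GTG	22356	-2.5	halve
BMSC_EVs	Thr-CGT	234	2.1	fragment
ASC_EVs	Arg-CCG	204	-3.5	halve
ASC_EVs	Phe-GAA	826	-3.0	fragment
ASC_EVs	Asn-GTT	147	2.8	fragment
ASC_EVs	Ile-AAT	545	2.6	fragment
ASC_EVs	Ala-TGC	1188	2.7	fragment
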