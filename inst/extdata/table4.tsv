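group	trna_name	percentage
ASCs	Gly-GCC	34.59
ASCs	Val-AAC	15.97
ASCs	Val-CAC	15.93
BMSCs	Gly-GCC	26.99
BMSCs	Val-CAC	8.46
BMSCs	Val-AAC	7.41
ASC_EVs	Gly-GCC	54.59
ASC_EVs	Glu-CTC	16.14
ASC_EVs	Gly-CCC	16.09
BMSC_EVs	Val-CAC	43.17
BMSC_EVs	Val-AAC	33.07
BMSC_EVs	Gly-GCC	13.07
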