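repeat_class	element_count	masked_bp	pct_genome
DNA/CMC-EnSpm	519278	255462349	3.64
DNA/MULE-MuDR	240450	77168806	1.10
DNA/PIF-Harbinger	721693	153386043	2.19
LINE/L1	236740	133767239	1.91
LTR/Copia	685340	1083387117	15.43
LTR/Gypsy	1357965	1951756200	27.80
Unknown	743186	286426659	4.08
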