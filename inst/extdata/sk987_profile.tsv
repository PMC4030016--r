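cell_line	gene	kind	magnitude
SK987	EGFR	overexpression	3
SK987	AKT1	overexpression	3
SK987	IL6	overexpression	3
SK987	PI3K	overexpression	3
SK987	CDKN2A	knockdown	5
SK987	CDKN2B	knockdown	5
SK987	RUNX3	knockdown	5
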