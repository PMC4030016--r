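cell_line	gene	kind	magnitude
COLO205	BRAF	activating_mutation	5
COLO205	CDKN2A	loss_of_function	5
HT29	BRAF	activating_mutation	5
HT29	CDKN2A	loss_of_function	5
HT29	MET	overexpression	3
MDAMB231	BRAF	activating_mutation	5
U266	BRAF	activating_mutation	5
H1650	BRAF	activating_mutation	5
H1650	CDKN2A	loss_of_function	5
H1975	BRAF	activating_mutation	5
H1975	CDKN2A	loss_of_function	5
SW48	BRAF	activating_mutation	5
SW48	CDKN2A	loss_of_function	5
AGS	CDH1	loss_of_function	5
AGS	MET	overexpression	3
H1437	CDH1	loss_of_function	5
H1437	CDKN2A	loss_of_function	5
MKN1	CDH1	loss_of_function	5
MKN45	CDH1	loss_of_function	5
MKN45	MET	overexpression	3
A549	MET	overexpression	3
A549	CDKN2A	loss_of_function	5
H358	MET	overexpression	3
BxPC3	CDKN2A	loss_of_function	5
HCT116	CDKN2A	loss_of_function	5
H460	CDKN2A	loss_of_function	5
SYN-ERBB2-1	ERBB2	overexpression	3
SYN-ERBB2-2	ERBB2	overexpression	3
SYN-ERBB2-2	CDKN2A	loss_of_function	5
SYN-CCND1-1	CCND1	overexpression	3
SYN-CCND1-2	CCND1	overexpression	3
SYN-CCND1-2	EGFR	overexpression	3
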