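# Reciprocal test-cross series A: Suri sires x Huacaya dams (9 half-sib families).
# n_huacaya = recessive-phenotype offspring, n_total = all offspring of that sire.
sire_id	sire_phen	dam_phen	n_huacaya	n_total
S0270100	Suri	Huacaya	3	9
S058104	Suri	Huacaya	2	11
S0810100	Suri	Huacaya	1	13
S237204	Suri	Huacaya	0	7
S244203	Suri	Huacaya	4	7
S443303	Suri	Huacaya	7	8
SEEI-024	Suri	Huacaya	6	15
SEEI-025	Suri	Huacaya	2	15
SSO-502	Suri	Huacaya	1	9
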