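# Reciprocal test-cross series B: Huacaya sires x Suri dams (8 half-sib families).
# Each dam contributes exactly one offspring, so the per-sire counts pool
# single-offspring matings; see single_offspring_set() for the matching design.
sire_id	sire_phen	dam_phen	n_huacaya	n_total
S035104	Huacaya	Suri	0	6
S095101	Huacaya	Suri	3	6
S1199-M	Huacaya	Suri	4	9
S148102	Huacaya	Suri	3	9
S216204	Huacaya	Suri	0	3
S322203	Huacaya	Suri	3	9
S366203	Huacaya	Suri	1	8
S370397	Huacaya	Suri	2	5
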