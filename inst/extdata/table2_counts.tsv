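# Suri x Suri half-sib series, as a frequency grid: n_males sires each with
# n_huacaya recessive offspring among n_total offspring. Expanded to one row
# per sire by load_fixture("table2"). Marginals: 57 sires, 57 Huacaya, 587 offspring.
n_huacaya	n_total	n_males
0	1	21
0	2	1
0	3	2
0	5	1
0	7	1
0	8	1
0	10	2
0	18	1
0	19	1
0	22	1
0	24	1
0	34	1
1	1	1
1	5	1
1	6	1
1	8	1
1	10	1
1	20	1
1	27	3
1	32	1
2	4	1
2	5	2
2	9	1
2	10	1
2	12	1
2	18	1
3	19	1
3	31	1
4	27	1
6	19	1
6	34	1
11	45	1
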