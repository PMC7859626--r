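weight_g	flow_lpm	cannula_fraction
500	0.03125	0.069444
500	0.0625	0.138889
500	0.125	0.277778
500	0.25	0.555556
500	0.5	1
500	0.75	1
500	1	1
500	1.5	1
500	2	1
750	0.03125	0.046296
750	0.0625	0.092593
750	0.125	0.185185
750	0.25	0.37037
750	0.5	0.740741
750	0.75	1
750	1	1
750	1.5	1
750	2	1
1000	0.03125	0.034722
1000	0.0625	0.069444
1000	0.125	0.138889
1000	0.25	0.277778
1000	0.5	0.555556
1000	0.75	0.833333
1000	1	1
1000	1.5	1
1000	2	1
1250	0.03125	0.027778
1250	0.0625	0.055556
1250	0.125	0.111111
1250	0.25	0.222222
1250	0.5	0.444444
1250	0.75	0.666667
1250	1	0.888889
1250	1.5	1
1250	2	1
1500	0.03125	0.023148
1500	0.0625	0.046296
1500	0.125	0.092593
1500	0.25	0.185185
1500	0.5	0.37037
1500	0.75	0.555556
1500	1	0.740741
1500	1.5	1
1500	2	1
2000	0.03125	0.017361
2000	0.0625	0.034722
2000	0.125	0.069444
2000	0.25	0.138889
2000	0.5	0.277778
2000	0.75	0.416667
2000	1	0.555556
2000	1.5	0.833333
2000	2	1
2500	0.03125	0.013889
2500	0.0625	0.027778
2500	0.125	0.055556
2500	0.25	0.111111
2500	0.5	0.222222
2500	0.75	0.333333
2500	1	0.444444
2500	1.5	0.666667
2500	2	0.888889
3000	0.03125	0.011574
3000	0.0625	0.023148
3000	0.125	0.046296
3000	0.25	0.092593
3000	0.5	0.185185
3000	0.75	0.277778
3000	1	0.37037
3000	1.5	0.555556
3000	2	0.740741
3500	0.03125	0.009921
3500	0.0625	0.019841
3500	0.125	0.039683
3500	0.25	0.079365
3500	0.5	0.15873
3500	0.75	0.238095
3500	1	0.31746
3500	1.5	0.47619
3500	2	0.634921
4000	0.03125	0.008681
4000	0.0625	0.017361
4000	0.125	0.034722
4000	0.25	0.069444
4000	0.5	0.138889
4000	0.75	0.208333
4000	1	0.277778
4000	1.5	0.416667
4000	2	0.555556
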