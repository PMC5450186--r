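group	n_loci	n_est_ssr	length_cM	density_printed
LG1	94	1	72.5	0.77
LG2	122	5	105.4	0.86
LG3	51	2	79.9	1.56
LG4	59	5	86.8	1.47
LG5	88	2	82.2	0.93
LG6	70	6	91.2	1.30
LG7	71	4	84.4	1.18
LG8	98	4	99.0	1.01
LG9	71	3	87.5	1.23
LG10	85	1	68.3	0.80
LG11	79	1	83.3	1.05
LG12	69	5	73.9	1.07
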