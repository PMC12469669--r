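locus	FIS	FIT	FST	Nm
Sat3	0.132	0.337	0.237	0.805
Sol33	0.018	0.232	0.217	0.902
Sol44	-0.079	-0.027	0.048	4.958
Sat5	0.027	0.090	0.065	3.596
D5Utr4a	-0.420	-0.103	0.223	0.871
D5Utr4b	0.665	0.908	0.725	0.095
D5Utr4c	-0.155	0.166	0.278	0.649
D5Utr4d	-0.693	-0.116	0.341	0.483
D5Utr4e	-0.135	-0.095	0.035	6.893
D5Utr4f	-0.042	0.054	0.092	2.467
D7Utr4a	0.048	0.299	0.264	0.697
D7Utr4b	-0.176	-0.173	0.002	NA
D19Utr4a	-0.191	-0.026	0.138	1.562
D19Utr4b	0.383	0.635	0.408	0.363
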