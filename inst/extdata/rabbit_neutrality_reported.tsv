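locus	BB	WB	RB	JAB	NZW	AR	CH
Sat3	0.842	-0.333	-1.000	-0.453	1.894	0.364	0.000
Sol33	1.770	-0.333	-1.000	0.119	0.494	0.000	0.667
Sol44	0.059	-0.636	1.080	-0.791	0.273	-1.636	-1.636
Sat5	0.970	-1.636	-0.448	-0.227	1.207	-1.636	-1.636
D5Utr4a	0.794	-1.333	-1.333	-1.386	0.767	-1.333	-1.333
D5Utr4b	-0.847	-1.000	-1.000	NA	-0.229	-1.000	-1.000
D5Utr4c	0.755	-1.333	-1.636	-1.333	-0.099	-1.333	-0.636
D5Utr4d	-1.006	-1.333	-1.333	NA	-0.606	-1.333	-1.333
D5Utr4e	2.413	-0.636	-0.636	NA	2.545	-1.333	-0.636
D5Utr4f	0.896	-2.181	NA	NA	2.335	-2.944	1.551
D7Utr4a	-0.144	-0.333	0.667	-1.152	0.351	-1.333	-0.333
D7Utr4b	0.807	-1.449	-0.190	1.054	0.028	-2.190	0.810
D19Utr4a	0.912	-1.333	-1.333	0.571	1.912	0.667	-1.333
D19Utr4b	-0.301	0.667	0.000	NA	-0.053	-1.000	-1.000
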