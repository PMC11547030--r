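Region	Length	A	T	G	C	AT	GC
Fulllength	15772	44.98	39.36	5.78	9.88	84.34	15.66
PCGs	10943	35.23	48.41	7.90	8.46	83.64	16.36
rrnL	1256	47.13	38.06	4.62	10.19	85.19	14.81
rrnS	767	43.02	40.68	5.74	10.56	83.70	16.30
tRNAs	1438	44.23	41.38	8.48	5.91	85.61	14.39
CR	1109	44.27	43.82	3.34	8.57	88.09	11.91
RR	193	50.78	35.23	4.15	9.84	86.01	13.99
plus_strand	7632	38.92	43.78	7.02	10.29	82.70	17.31
minus_strand	6829	51.66	33.86	4.83	9.65	85.52	14.48
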