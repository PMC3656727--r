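locus_id	n	amplicon_bp	sequenced_bp	s	singletons	h	hd	theta_w_x1000	pi_x1000	tajimas_d	d_significant
PaAP2L3	74	4681	457	5	1	7	0.58	2.2	1.8	-0.42	FALSE
PaCDF1	107	1585	1028	23	4	22	0.92	4.3	2.9	-0.94	FALSE
PaCOL1	81	2970	2449	64	26	39	0.97	5.3	3.3	-1.22	FALSE
PaMFT1	96	4328	1597	62	34	54	0.95	7.6	3.3	-1.81	TRUE
PaFTL1	109	2742	748	14	4	14	0.82	3.6	3.3	-0.18	FALSE
PaCCA1	88	4126	742	24	5	21	0.90	6.4	4.1	-1.10	FALSE
PaPRR7	93	7271	1796	31	21	23	0.88	3.4	1.6	-1.65	FALSE
PaPRR1	114	1859	986	25	8	20	0.89	4.8	4.8	0.02	FALSE
PaWS02746	97	4411	470	34	13	40	0.96	14.1	12.0	-0.43	FALSE
PaWS02749	100	3189	605	53	20	23	0.82	16.9	10.5	-1.21	FALSE
PaZIP	113	4107	803	21	6	15	0.74	4.9	3.6	-0.78	FALSE
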