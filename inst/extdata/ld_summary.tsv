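locus_id	informative_sites	n_pairs	pct_significant	mean_r2	decay_bp_r2_02	rho	rho_per_site	rho_over_theta
PaAP2L3	4	6	16.7	NA	NA	2.04	0.0004	1.98
PaCDF1	19	171	6.4	0.041	0	5.10	0.003	1.16
PaCOL1	38	703	6.3	0.079	74	18.4	0.006	1.42
PaMFT1	28	378	15	0.056	12	25.5	0.006	2.11
PaFTL1	10	45	28.9	0.13	5	19.4	0.007	7.29
PaCCA1	18	153	8.5	0.069	7	11.2	0.003	2.36
PaPRR7	10	45	20	0.097	88	8.16	0.001	1.34
PaPRR1	17	136	30.9	0.17	96	3.06	0.002	0.65
PaWS02746	19	171	21.6	0.14	118	21.4	0.005	3.24
PaWS02749	31	465	11.8	0.12	59	11.2	0.004	1.10
PaZIP	15	105	26.7	0.2	353	0	0	0
all_loci	209	2378	11.4	0.1	46	11.4	0.003	1.81
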