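# Published per-case results of the pruning+mimotope method ("pruned") and
# of plain MimoPro ("mimopro") on the standard 18-complex phage-display
# benchmark (residue-level metrics over the antigen surface universe).
case	true_epitopes	predicted_mimopro	predicted_pruned	sen_mimopro	sen_pruned	spe_mimopro	spe_pruned	ppv_mimopro	ppv_pruned	mcc_mimopro	mcc_pruned	acc_mimopro	acc_pruned	f_mimopro	f_pruned
3IU3_I	23	34	32	0.61	0.61	0.75	0.78	0.41	0.44	0.18	0.19	0.72	0.74	0.49	0.51
1YY9_A	15	43	18	0.00	0.00	0.91	0.96	0.00	0.00	-0.01	-0.01	0.88	0.93	0.00	0.00
1N8Z_C	20	38	36	0.90	0.85	0.95	0.95	0.47	0.47	0.14	0.13	0.95	0.95	0.62	0.61
2ADF_A	15	24	20	0.87	0.87	0.90	0.94	0.54	0.65	0.23	0.25	0.90	0.93	0.67	0.74
1IQD_C	16	40	37	0.56	0.50	0.68	0.70	0.23	0.22	0.08	0.07	0.66	0.67	0.32	0.30
2GHW_A	29	38	37	0.48	0.48	0.80	0.81	0.37	0.38	0.13	0.14	0.73	0.74	0.42	0.42
2NY7_G	25	30	29	0.12	0.12	0.87	0.87	0.10	0.10	0.00	0.00	0.78	0.79	0.11	0.11
1G9M_G	15	47	46	0.73	0.73	0.83	0.84	0.23	0.24	0.10	0.10	0.83	0.83	0.35	0.36
1E6J_P	11	45	43	0.73	0.73	0.77	0.79	0.18	0.19	0.08	0.08	0.77	0.78	0.29	0.30
1ZTX_E	14	39	37	0.10	0.10	0.63	0.66	0.36	0.38	0.24	0.24	0.69	0.72	0.53	0.55
2AJF_A	20	43	39	0.10	0.10	0.90	0.91	0.05	0.05	0.00	0.00	0.86	0.87	0.06	0.07
1BJ1_W	19	32	32	0.68	0.68	0.72	0.72	0.41	0.41	0.19	0.19	0.72	0.72	0.51	0.51
1JRH_I	21	31	30	0.95	0.90	0.82	0.82	0.65	0.63	0.38	0.36	0.85	0.84	0.77	0.75
1AVZ_B	16	32	31	0.69	0.69	0.71	0.72	0.34	0.35	0.16	0.17	0.70	0.72	0.46	0.47
1HX1_B	20	38	38	0.75	0.75	0.69	0.69	0.39	0.39	0.20	0.20	0.70	0.70	0.52	0.52
2GSK_A	33	40	37	0.21	0.21	0.93	0.93	0.18	0.19	0.04	0.04	0.88	0.88	0.19	0.20
3EZE_B	20	27	26	0.75	0.70	0.74	0.74	0.56	0.54	0.29	0.27	0.75	0.73	0.64	0.61
1II4_A	30	41	39	0.60	0.60	0.69	0.72	0.44	0.46	0.18	0.19	0.66	0.68	0.51	0.52
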