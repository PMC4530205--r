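factor	n	low_exposed	n_exposed	low_unexposed	n_unexposed	or_printed	ci_lo_printed	ci_hi_printed
b2m_ge_3.5	137	44	82	14	55	3.39	1.61	7.15
b2m_gt_5.5	137	28	43	30	94	3.98	1.86	8.54
hb_lt_10	139	27	43	33	96	3.22	1.52	6.81
crp_ge_8	139	27	45	33	94	2.77	1.33	5.76
ldh_ge_190	139	21	31	39	108	3.72	1.59	8.69
bmpc_ge_33	134	49	93	10	41	3.45	1.52	7.85
cytogenetic_abn	136	30	57	28	79	2.02	1.01	4.05
gep70_high	139	20	32	40	107	2.79	1.23	6.31
gep80_high	139	11	16	49	123	3.32	1.09	10.15
ms_subgroup	139	4	20	56	119	0.28	0.09	0.89
centrosome_ge_3	139	41	69	19	70	3.93	1.93	8.02
stem_lines_gt_2	139	11	17	49	122	2.73	0.95	7.87
lcr_gt_50	139	21	28	39	111	5.54	2.16	14.18
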