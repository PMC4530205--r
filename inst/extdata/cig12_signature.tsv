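probe_id	symbol	chromosome	mean_low_cig	mean_high_cig
239844_x_at	C1orf228	chr1p34.1	6.581345	7.389482
213187_x_at	FTL	chr19q13.33	14.14725	14.52846
215432_at	ACSM1	chr16p12.3	4.267809	5.102535
226286_at	ELMOD3	chr2p11.2	8.116286	8.691678
209776_s_at	SLC19A1	chr21q22.3	6.504695	5.352083
217622_at	RHBDD3	chr22q12.2	8.329782	8.782621
212788_x_at	FTL	chr19q13.33	14.7247	15.07511
227896_at	BCCIP	chr10q26.1	8.344684	7.80806
215949_x_at	IGHM	chr14q32.33	9.263938	11.03889
219117_s_at	FKBP11	chr12q13.12	14.69882	15.04902
207408_at	SLC22A14	chr3p21.3	8.967901	9.309341
204251_s_at	CEP164	chr11q23.3	8.27905	7.790321
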