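sample_id	group	treatment	pH	SMC	NH4	NO3	IN	DOC	DON	TC	TN	comm_axis1	comm_axis2	biomass	yield
CK_1	CK	-1.19024	-0.417481	-1.11647	-0.6645	-0.371065	-0.820022	-0.994654	-0.838769	-0.998327	-0.939297	-0.796347	-1.32258	-0.232081	-0.434053
CK_2	CK	-1.19024	-1.52019	-2.60003	-2.05802	-1.45288	-1.79213	-1.89801	-1.56854	-1.93571	-2.00152	-1.64367	-1.52613	-1.37161	-2.03468
CK_3	CK	-1.19024	-0.837211	-1.25563	-1.04485	-1.05999	-0.799077	-0.972772	-1.36637	-1.32651	-1.50419	-1.45627	-1.97494	-1.56003	-1.10343
CK_4	CK	-1.19024	-0.247623	-0.338031	0.167739	-0.181416	-0.66449	-0.367415	-0.686842	-0.104831	-0.281985	-0.374854	-0.94929	-0.343507	-0.0632725
CK_5	CK	-1.19024	-0.872713	-1.73911	-1.39731	-1.62749	-1.39912	-1.29727	-1.45898	-0.805065	-1.2072	-1.79543	-1.18839	-1.59887	-0.869107
CK_6	CK	-1.19024	-1.06043	-0.622408	-1.31414	-1.04842	-0.609888	-0.767267	-1.15481	-1.08031	-1.04656	-0.154491	-0.673783	-0.905285	-1.47267
M_1	M	0	0.0349287	0.270436	0.353644	0.218169	0.94477	0.831517	0.512549	-0.0613514	0.286427	-0.0699667	0.395606	0.452447	-0.0401883
M_2	M	0	0.116223	-0.0402288	0.175015	0.565792	0.0488153	0.109329	0.113301	-0.327117	-0.231	-0.390692	0.296347	0.0859998	-0.528811
M_3	M	0	-0.79146	-0.567035	-0.572909	-0.572014	-0.794076	-0.485569	-0.78576	-0.534617	-0.741651	-0.463382	-0.663524	-0.600989	-0.102641
M_4	M	0	-1.36629	-1.36155	-1.72387	-0.739823	-0.997162	-1.39784	-1.15853	-1.2446	-1.46203	-0.254063	-0.482741	-0.561509	-0.793518
M_5	M	0	1.55944	1.67729	1.10773	1.18722	0.963729	1.74975	0.960859	1.6071	1.39847	0.183176	0.156974	0.584495	0.754091
M_6	M	0	-0.846518	-1.13328	-1.37136	-0.767675	-1.0193	-0.168009	-0.846896	-1.11266	-0.599758	-0.290778	-0.787905	-0.749389	-0.781164
bioM_1	bioM	1.19024	0.281968	0.0415317	0.662478	-0.279604	0.291216	0.264526	0.651956	-0.120046	0.270191	1.73684	0.96428	0.90161	0.423177
bioM_2	bioM	1.19024	1.60991	1.65661	1.93292	1.85621	1.40622	1.95016	1.7257	2.22435	1.91045	1.84257	1.53712	1.09477	1.49521
bioM_3	bioM	1.19024	1.25534	0.853919	1.65237	1.58301	1.17555	1.32992	1.56684	1.48115	1.67987	1.46217	1.24344	0.59936	1.59593
bioM_4	bioM	1.19024	2.48576	2.54526	2.53548	2.62325	2.68679	1.83581	2.67424	2.16507	2.14904	1.8735	1.91424	2.00435	2.49527
bioM_5	bioM	1.19024	1.83721	2.16732	1.40532	1.95792	2.10579	1.61976	1.67096	1.61586	1.97847	0.357095	1.03181	1.4716	1.85251
bioM_6	bioM	1.19024	-0.535027	-0.427453	-0.817107	-0.612257	-0.740811	-0.166297	-0.374855	-0.583759	-0.705762	0.0044636	-0.0527457	0.0197981	-0.0792653
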