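taxon_id	CK_1	CK_2	CK_3	CK_4	CK_5	CK_6	M_1	M_2	M_3	M_4	M_5	M_6	bioM_1	bioM_2	bioM_3	bioM_4	bioM_5	bioM_6
ASV_0001	13	2	41	4	16	4	16	16	22	77	14	2	51	21	63	19	37	53
ASV_0002	2	0	25	15	12	9	9	38	34	21	3	2	7	31	48	47	8	29
ASV_0003	71	88	350	635	631	935	518	370	1147	642	474	81	219	328	1247	940	166	439
ASV_0004	2	0	17	3	15	2	36	20	13	6	12	3	5	5	7	13	4	24
ASV_0005	30	56	204	32	90	50	33	365	302	100	76	22	43	18	148	170	91	167
ASV_0006	1	4	7	2	9	6	10	9	3	9	6	0	7	8	10	2	8	10
ASV_0007	1	0	1	1	1	2	3	3	3	2	2	1	2	4	0	1	0	0
ASV_0008	0	0	1	0	0	0	0	0	1	0	2	0	0	0	0	0	1	1
ASV_0009	3	3	30	21	22	58	18	8	12	14	5	1	20	35	5	31	11	28
ASV_0010	0	1	1	0	1	2	2	0	2	1	0	2	2	0	0	2	1	4
ASV_0011	4	2	22	0	10	13	14	7	22	2	7	1	13	29	0	7	5	8
ASV_0012	29	3	394	22	56	85	247	212	298	100	92	5	109	218	192	97	51	439
ASV_0013	3	0	25	2	29	12	5	4	3	8	17	0	7	13	5	6	13	18
ASV_0014	1	1	3	12	1	2	7	18	3	3	3	2	3	4	9	8	5	10
ASV_0015	0	0	0	0	0	0	0	0	2	1	0	0	0	2	2	1	0	3
ASV_0016	0	0	1	1	5	1	0	1	8	1	4	0	4	2	3	13	0	3
ASV_0017	3	1	0	0	1	4	0	3	2	5	4	0	0	0	0	2	0	3
ASV_0018	10	3	49	7	42	28	10	25	17	17	20	1	17	61	18	27	7	48
ASV_0019	6	3	5	9	57	15	22	21	26	3	14	0	3	3	16	8	7	3
ASV_0020	3	1	11	17	9	4	9	32	13	23	10	0	22	0	1	8	3	38
ASV_0021	74	24	2	46	8	16	1	16	0	3	10	28	12	1	29	2	16	2
ASV_0022	96	0	3	3	4	11	8	4	1	7	10	13	7	1	18	0	5	1
ASV_0023	54	9	1	17	1	14	2	23	3	7	12	3	8	1	25	5	30	2
ASV_0024	43	12	3	29	12	13	17	66	4	2	22	27	8	1	8	3	27	4
ASV_0025	54	11	0	34	8	34	20	1	3	1	29	7	83	2	44	8	66	40
ASV_0026	185	53	18	233	65	315	429	293	45	248	238	1174	112	13	465	58	462	35
ASV_0027	27	0	2	29	1	1	6	3	0	0	2	1	0	0	2	0	0	1
ASV_0028	700	109	18	647	63	280	52	96	73	39	380	28	117	5	9	3	28	11
ASV_0029	52	20	3	39	55	67	72	54	4	4	52	9	2	0	0	2	6	0
ASV_0030	11	0	0	2	0	1	2	2	0	0	2	3	0	1	3	0	1	0
ASV_0031	3	6	1	3	2	8	8	13	0	1	9	4	4	1	10	0	6	4
ASV_0032	28	2	0	0	5	9	11	23	3	0	7	16	0	0	4	1	0	1
ASV_0033	8	1	0	2	4	1	2	6	1	1	2	1	0	0	1	0	0	0
ASV_0034	8	0	0	1	0	1	1	2	0	0	1	1	0	0	3	0	0	0
ASV_0035	2	4	1	45	17	3	5	1	1	0	1	12	0	0	0	0	0	0
ASV_0036	27	1	2	12	6	2	6	2	2	3	3	7	0	0	6	1	4	2
ASV_0037	27	1	0	3	5	7	2	6	1	0	17	8	3	1	12	0	7	3
ASV_0038	2	0	0	3	0	0	0	0	0	0	0	0	0	0	0	0	1	0
ASV_0039	73	4	2	17	6	8	9	8	1	2	31	15	29	1	48	9	49	4
ASV_0040	85	45	2	126	27	12	9	15	21	9	125	31	20	2	31	1	27	4
ASV_0041	17	10	2	16	59	1	4	5	15	59	28	5	52	32	26	32	17	19
ASV_0042	15	110	5	88	35	5	1	34	4	28	15	4	50	39	15	30	17	30
ASV_0043	9	63	3	7	14	4	1	8	1	33	2	5	5	14	5	18	11	0
ASV_0044	59	263	48	18	185	11	65	62	11	56	19	68	124	57	296	23	217	27
ASV_0045	6	1	2	4	5	0	0	2	1	3	17	0	4	7	35	4	4	5
ASV_0046	2	7	2	2	4	0	1	2	1	3	2	0	3	1	1	1	0	0
ASV_0047	8	23	4	43	49	7	5	51	0	14	23	2	33	30	59	7	5	25
ASV_0048	24	46	0	22	13	7	7	10	7	49	13	3	5	111	47	12	10	14
ASV_0049	0	5	1	1	0	1	0	1	0	3	5	0	7	8	5	8	5	0
ASV_0050	5	19	2	10	0	5	3	12	7	44	103	12	26	3	20	16	6	11
ASV_0051	15	61	10	21	19	5	0	6	2	23	19	0	30	22	19	5	23	8
ASV_0052	2	10	3	23	25	10	1	20	7	33	42	4	4	11	5	28	9	3
ASV_0053	20	118	3	105	93	14	27	16	8	76	93	24	32	239	240	15	177	67
ASV_0054	49	74	11	55	31	5	12	35	28	82	69	6	15	22	153	41	34	10
ASV_0055	0	1	0	1	1	0	0	0	0	0	1	0	0	0	4	1	0	0
ASV_0056	65	73	20	191	169	54	4	41	4	147	14	1	77	30	146	106	33	17
ASV_0057	13	23	9	8	6	4	4	12	8	23	130	31	47	16	10	10	22	50
ASV_0058	2	0	1	11	7	2	4	3	0	7	2	0	6	9	28	7	11	10
ASV_0059	1	5	1	5	3	0	0	1	0	5	12	0	2	2	2	1	0	3
ASV_0060	51	49	16	33	14	1	11	44	10	108	220	17	70	69	62	18	98	24
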