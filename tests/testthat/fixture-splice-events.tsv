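event_id	type	gene_id	chrom	strand	body_start	body_end	body2_start	body2_end	inc_L0_r1	inc_L0_r2	inc_L4_r1	inc_L4_r2	inc_L8_r1	inc_L8_r2	inc_N0_r1	inc_N0_r2	exc_L0_r1	exc_L0_r2	exc_L4_r1	exc_L4_r2	exc_L8_r1	exc_L8_r2	exc_N0_r1	exc_N0_r2
ev0001	SE	sg0001	chrS	+	999	1066	NA	NA	38	36	32	40	39	38	37	41	22	24	28	20	21	22	23	19
ev0002	MXE	sg0002	chrS	+	2999	3067	3367	3490	34	28	32	28	29	38	33	34	26	32	28	32	31	22	27	26
ev0003	MXE	sg0003	chrS	-	4999	5089	5389	5521	26	25	33	46	46	41	43	47	34	35	27	14	14	19	17	13
ev0004	SE	sg0004	chrS	+	6999	7090	NA	NA	36	40	30	32	28	48	40	33	24	20	30	28	32	12	20	27
ev0005	SE	sg0005	chrS	-	8999	9065	NA	NA	19	24	44	38	41	43	44	41	41	36	16	22	19	17	16	19
ev0006	A3SS	sg0006	chrS	+	10999	11127	NA	NA	35	34	40	40	36	31	32	34	25	26	20	20	24	29	28	26
ev0007	A5SS	sg0007	chrS	+	12999	13116	NA	NA	35	35	54	54	54	53	56	58	25	25	6	6	6	7	4	2
ev0008	MXE	sg0008	chrS	+	14999	15091	15391	15476	41	45	27	21	13	20	19	19	19	15	33	39	47	40	41	41
ev0009	MXE	sg0009	chrS	-	16999	17100	17400	17475	28	36	29	26	30	29	37	30	32	24	31	34	30	31	23	30
ev0010	RI	sg0010	chrS	-	18999	19108	NA	NA	42	43	23	22	23	29	15	16	18	17	37	38	37	31	45	44
ev0011	SE	sg0011	chrS	+	20999	21089	NA	NA	17	18	21	18	14	15	15	16	43	42	39	42	46	45	45	44
ev0012	SE	sg0012	chrS	+	22999	23067	NA	NA	35	37	31	38	36	30	32	32	25	23	29	22	24	30	28	28
ev0013	A5SS	sg0013	chrS	-	24999	25143	NA	NA	38	44	41	40	33	36	39	42	22	16	19	20	27	24	21	18
ev0014	SE	sg0014	chrS	-	26999	27146	NA	NA	34	30	56	55	58	58	57	50	26	30	4	5	2	2	3	10
ev0015	SE	sg0015	chrS	-	28999	29109	NA	NA	33	33	32	26	27	32	30	33	27	27	28	34	33	28	30	27
ev0016	SE	sg0016	chrS	+	30999	31102	NA	NA	25	29	30	40	22	25	30	31	35	31	30	20	38	35	30	29
ev0017	SE	sg0017	chrS	-	32999	33091	NA	NA	12	16	18	10	17	11	14	13	48	44	42	50	43	49	46	47
ev0018	MXE	sg0018	chrS	-	34999	35145	35445	35549	13	13	20	22	18	15	16	17	47	47	40	38	42	45	44	43
ev0019	A3SS	sg0019	chrS	-	36999	37126	NA	NA	38	40	41	46	45	39	31	42	22	20	19	14	15	21	29	18
ev0020	SE	sg0020	chrS	+	38999	39139	NA	NA	26	29	35	27	40	31	38	26	34	31	25	33	20	29	22	34
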