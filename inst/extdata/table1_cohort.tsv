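Sample	Age	Gender	Pathology	Grade	Stage	IDH1	Survival_months	RNAseq	Patient
MG1	63	Female	Glioblastoma	IV	Recurrent	WT	5	Yes
MG2	77	Male	Glioblastoma	IV	Recurrent	WT	9	Yes
MG3	67	Female	Glioblastoma	IV	Primary	WT	51	Yes
MG4	30	Female	Anaplastic astrocytoma	III	Primary	WT	44	Yes
MG5	69	Male	Glioblastoma	IV	Primary	WT	3.5	Yes
MG6	49	Male	Glioblastoma	IV	Recurrent	WT	5.5	Yes
MG7	63	Male	Oligodendroglioma	II	Primary	Mut	69	Yes
MG8	76	Male	Glioblastoma	IV	Primary	WT	14	No
MG9	25	Male	Anaplastic oligodendroglioma	III	Primary	Mut	66	Yes
MG10	38	Female	Oligodendroglioma	II	Primary	Mut	65	Yes
MG11	46	Male	Anaplastic oligodendroglioma	III	Primary	Mut	64	Yes
MG12	54	Female	Glioblastoma	IV	Recurrent	WT	8	Yes
MG13	30	Female	Anaplastic oligodendroglioma	III	Primary	Mut	50	Yes
MG14	63	Female	Anaplastic oligodendroglioma	III	Primary	Mut	25	Yes
MG15	49	Female	Glioblastoma	IV	Primary	WT	4	Yes
MG16	48	Male	Oligodendroglioma	II	Primary	Mut	21	Yes
MG17	33	Female	Oligodendroglioma	II	Primary	Mut	14	Yes
MG18	40	Female	Anaplastic astrocytoma	III	Primary	-	34	No	P1
MG19	43	Female	Glioblastoma	IV	Recurrent	-	4	No	P1
MG20	44	Female	Glioblastoma	IV	Primary	Mut	53	No	P2
MG21	48	Female	Glioblastoma	IV	Recurrent	Mut	7	No	P2
MG22	64	Male	Glioblastoma	IV	Primary	WT	5	No
MG23	32	Female	Glioblastoma	IV	Recurrent	-	41	No
MG24	55	Male	Anaplastic oligodendroglioma	III	Primary	Mut	97	No
MG25	47	Male	Astrocytoma	II	Primary	Mut	88	No
MG26	31	Male	Anaplastic astrocytoma	III	Primary	Mut	89	No
MG27	58	Female	Glioblastoma	IV	Primary	WT	16	No	P3
MG28	58	Female	Glioblastoma	IV	Recurrent	WT	13	No	P3
MG29	63	Male	Glioblastoma	IV	Recurrent	-	4	No
MG30	49	Male	Glioblastoma	IV	Recurrent	WT	14	No
MG31	55	Male	Oligodendroglioma	II	Primary	Mut	58	No
MG32	32	Male	Astrocytoma	II	Primary	Mut	57	No
MG33	49	Female	Glioblastoma	IV	Primary	WT	16	No
MG34	21	Female	Glioblastoma	IV	Recurrent	WT	5	No
MG35	50	Male	Glioblastoma	IV	Recurrent	Mut	5	No
MG36	69	Female	Glioblastoma	IV	Primary	WT	12	No
MG37	37	Female	Glioblastoma	IV	Recurrent	Mut	39	No
MG38	66	Male	Anaplastic oligodendroglioma	III	Primary	WT	18	No
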