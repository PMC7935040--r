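region_id	region_name	hemisphere
0	Precentral_L	left
1	Precentral_R	right
2	Frontal_Sup_2_L	left
3	Frontal_Sup_2_R	right
4	Frontal_Mid_2_L	left
5	Frontal_Mid_2_R	right
6	Frontal_Inf_Oper_L	left
7	Frontal_Inf_Oper_R	right
8	Frontal_Inf_Tri_L	left
9	Frontal_Inf_Tri_R	right
10	Frontal_Inf_Orb_2_L	left
11	Frontal_Inf_Orb_2_R	right
12	Rolandic_Oper_L	left
13	Rolandic_Oper_R	right
14	Supp_Motor_Area_L	left
15	Supp_Motor_Area_R	right
16	Olfactory_L	left
17	Olfactory_R	right
18	Frontal_Sup_Medial_L	left
19	Frontal_Sup_Medial_R	right
20	Frontal_Med_Orb_L	left
21	Frontal_Med_Orb_R	right
22	Rectus_L	left
23	Rectus_R	right
24	OFCmed_L	left
25	OFCmed_R	right
26	OFCant_L	left
27	OFCant_R	right
28	OFCpost_L	left
29	OFCpost_R	right
30	OFClat_L	left
31	OFClat_R	right
32	Insula_L	left
33	Insula_R	right
34	Cingulate_Ant_L	left
35	Cingulate_Ant_R	right
36	Cingulate_Mid_L	left
37	Cingulate_Mid_R	right
38	Cingulate_Post_L	left
39	Cingulate_Post_R	right
40	Hippocampus_L	left
41	Hippocampus_R	right
42	ParaHippocampal_L	left
43	ParaHippocampal_R	right
44	Amygdala_L	left
45	Amygdala_R	right
46	Calcarine_L	left
47	Calcarine_R	right
48	Cuneus_L	left
49	Cuneus_R	right
50	Lingual_L	left
51	Lingual_R	right
52	Occipital_Sup_L	left
53	Occipital_Sup_R	right
54	Occipital_Mid_L	left
55	Occipital_Mid_R	right
56	Occipital_Inf_L	left
57	Occipital_Inf_R	right
58	Fusiform_L	left
59	Fusiform_R	right
60	Postcentral_L	left
61	Postcentral_R	right
62	Parietal_Sup_L	left
63	Parietal_Sup_R	right
64	Parietal_Inf_L	left
65	Parietal_Inf_R	right
66	SupraMarginal_L	left
67	SupraMarginal_R	right
68	Angular_L	left
69	Angular_R	right
70	Precuneus_L	left
71	Precuneus_R	right
72	Paracentral_Lobule_L	left
73	Paracentral_Lobule_R	right
74	Caudate_L	left
75	Caudate_R	right
76	Putamen_L	left
77	Putamen_R	right
78	Pallidum_L	left
79	Pallidum_R	right
80	Thalamus_L	left
81	Thalamus_R	right
82	Heschl_L	left
83	Heschl_R	right
84	Temporal_Sup_L	left
85	Temporal_Sup_R	right
86	Temporal_Pole_Sup_L	left
87	Temporal_Pole_Sup_R	right
88	Temporal_Mid_L	left
89	Temporal_Mid_R	right
90	Temporal_Pole_Mid_L	left
91	Temporal_Pole_Mid_R	right
92	Temporal_Inf_L	left
93	Temporal_Inf_R	right
94	Cerebelum_Crus1_L	left
95	Cerebelum_Crus1_R	right
96	Cerebelum_Crus2_L	left
97	Cerebelum_Crus2_R	right
98	Cerebelum_3_L	left
99	Cerebelum_3_R	right
100	Cerebelum_4_5_L	left
101	Cerebelum_4_5_R	right
102	Cerebelum_6_L	left
103	Cerebelum_6_R	right
104	Cerebelum_7b_L	left
105	Cerebelum_7b_R	right
106	Cerebelum_8_L	left
107	Cerebelum_8_R	right
108	Cerebelum_9_L	left
109	Cerebelum_9_R	right
110	Cerebelum_10_L	left
111	Cerebelum_10_R	right
112	Vermis_1_2	none
113	Vermis_3	none
114	Vermis_4_5	none
115	Vermis_6	none
116	Vermis_7	none
117	Vermis_8	none
118	Vermis_9	none
119	Vermis_10	none
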