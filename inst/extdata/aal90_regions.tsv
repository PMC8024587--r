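index	abbrev	name	hemisphere
1	PreCG.L	Precentral gyrus (L)	L
2	PreCG.R	Precentral gyrus (R)	R
3	SFGdor.L	Superior frontal gyrus, dorsolateral (L)	L
4	SFGdor.R	Superior frontal gyrus, dorsolateral (R)	R
5	ORBsup.L	Superior frontal gyrus, orbital part (L)	L
6	ORBsup.R	Superior frontal gyrus, orbital part (R)	R
7	MFG.L	Middle frontal gyrus (L)	L
8	MFG.R	Middle frontal gyrus (R)	R
9	ORBmid.L	Middle frontal gyrus, orbital part (L)	L
10	ORBmid.R	Middle frontal gyrus, orbital part (R)	R
11	IFGoperc.L	Inferior frontal gyrus, opercular part (L)	L
12	IFGoperc.R	Inferior frontal gyrus, opercular part (R)	R
13	IFGtriang.L	Inferior frontal gyrus, triangular part (L)	L
14	IFGtriang.R	Inferior frontal gyrus, triangular part (R)	R
15	ORBinf.L	Inferior frontal gyrus, orbital part (L)	L
16	ORBinf.R	Inferior frontal gyrus, orbital part (R)	R
17	ROL.L	Rolandic operculum (L)	L
18	ROL.R	Rolandic operculum (R)	R
19	SMA.L	Supplementary motor area (L)	L
20	SMA.R	Supplementary motor area (R)	R
21	OLF.L	Olfactory cortex (L)	L
22	OLF.R	Olfactory cortex (R)	R
23	SFGmed.L	Superior frontal gyrus, medial (L)	L
24	SFGmed.R	Superior frontal gyrus, medial (R)	R
25	ORBsupmed.L	Superior frontal gyrus, medial orbital (L)	L
26	ORBsupmed.R	Superior frontal gyrus, medial orbital (R)	R
27	REC.L	Gyrus rectus (L)	L
28	REC.R	Gyrus rectus (R)	R
29	INS.L	Insula (L)	L
30	INS.R	Insula (R)	R
31	ACG.L	Anterior cingulate and paracingulate gyri (L)	L
32	ACG.R	Anterior cingulate and paracingulate gyri (R)	R
33	DCG.L	Median cingulate and paracingulate gyri (L)	L
34	DCG.R	Median cingulate and paracingulate gyri (R)	R
35	PCG.L	Posterior cingulate gyrus (L)	L
36	PCG.R	Posterior cingulate gyrus (R)	R
37	HIP.L	Hippocampus (L)	L
38	HIP.R	Hippocampus (R)	R
39	PHG.L	Parahippocampal gyrus (L)	L
40	PHG.R	Parahippocampal gyrus (R)	R
41	AMYG.L	Amygdala (L)	L
42	AMYG.R	Amygdala (R)	R
43	CAL.L	Calcarine fissure and surrounding cortex (L)	L
44	CAL.R	Calcarine fissure and surrounding cortex (R)	R
45	CUN.L	Cuneus (L)	L
46	CUN.R	Cuneus (R)	R
47	LING.L	Lingual gyrus (L)	L
48	LING.R	Lingual gyrus (R)	R
49	SOG.L	Superior occipital gyrus (L)	L
50	SOG.R	Superior occipital gyrus (R)	R
51	MOG.L	Middle occipital gyrus (L)	L
52	MOG.R	Middle occipital gyrus (R)	R
53	IOG.L	Inferior occipital gyrus (L)	L
54	IOG.R	Inferior occipital gyrus (R)	R
55	FFG.L	Fusiform gyrus (L)	L
56	FFG.R	Fusiform gyrus (R)	R
57	PoCG.L	Postcentral gyrus (L)	L
58	PoCG.R	Postcentral gyrus (R)	R
59	SPG.L	Superior parietal gyrus (L)	L
60	SPG.R	Superior parietal gyrus (R)	R
61	IPL.L	Inferior parietal, supramarginal and angular gyri (L)	L
62	IPL.R	Inferior parietal, supramarginal and angular gyri (R)	R
63	SMG.L	Supramarginal gyrus (L)	L
64	SMG.R	Supramarginal gyrus (R)	R
65	ANG.L	Angular gyrus (L)	L
66	ANG.R	Angular gyrus (R)	R
67	PCUN.L	Precuneus (L)	L
68	PCUN.R	Precuneus (R)	R
69	PCL.L	Paracentral lobule (L)	L
70	PCL.R	Paracentral lobule (R)	R
71	CAU.L	Caudate nucleus (L)	L
72	CAU.R	Caudate nucleus (R)	R
73	PUT.L	Lenticular nucleus, putamen (L)	L
74	PUT.R	Lenticular nucleus, putamen (R)	R
75	PAL.L	Lenticular nucleus, pallidum (L)	L
76	PAL.R	Lenticular nucleus, pallidum (R)	R
77	THA.L	Thalamus (L)	L
78	THA.R	Thalamus (R)	R
79	HES.L	Heschl gyrus (L)	L
80	HES.R	Heschl gyrus (R)	R
81	STG.L	Superior temporal gyrus (L)	L
82	STG.R	Superior temporal gyrus (R)	R
83	TPOsup.L	Temporal pole: superior temporal gyrus (L)	L
84	TPOsup.R	Temporal pole: superior temporal gyrus (R)	R
85	MTG.L	Middle temporal gyrus (L)	L
86	MTG.R	Middle temporal gyrus (R)	R
87	TPOmid.L	Temporal pole: middle temporal gyrus (L)	L
88	TPOmid.R	Temporal pole: middle temporal gyrus (R)	R
89	ITG.L	Inferior temporal gyrus (L)	L
90	ITG.R	Inferior temporal gyrus (R)	R
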