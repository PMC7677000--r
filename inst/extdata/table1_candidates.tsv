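feature_id	rt_seconds	mz	ion_mode	ratio_vs_b313	p_value	vip	strain	compound	cas
M190T192	192	190	positive	84.57	1.50e-05	2.51	B108	kynurenic acid	492-27-3
M115T124	124	115	positive	116.47	4.55e-08	3.02	B253	ethylmalonic acid	601-75-2
M131T125	125	131	negative	272.19	2.05e-09	3.82	B253	glutaric acid	110-94-1
M145T115	115	145	negative	35.59	6.98e-13	3.08	B253	adipic acid	124-04-9
M125T103	103	125	negative	16.01	9.73e-07	2.27	B253	thymine	65-71-4
M124T65	65	124	positive	1552.84	4.14e-06	6.40	B263	picolinic acid	98-98-6
M124T82	82	124	positive	546.33	5.32e-09	5.57	B263	picolinic acid	98-98-6
M137T63	63	137	positive	96.63	1.00e-10	4.74	B263	hypoxanthine	68-94-0
M115T124	124	115	positive	79.63	7.77e-08	4.69	B263	ethylmalonic acid	601-75-2
M176T307	307	176	positive	54.29	6.79e-17	3.65	B263	indoleacetic acid	87-51-4
M137T84	84	137	positive	40.63	4.43e-07	3.83	B263	hypoxanthine	68-94-0
M135T84	84	135	negative	379.16	1.45e-07	5.41	B263	hypoxanthine	68-94-0
M131T125	125	131	negative	211.67	5.44e-09	4.61	B263	glutaric acid	110-94-1
M145T115	115	145	negative	27.01	1.04e-11	3.58	B263	adipic acid	124-04-9
M125T103	103	125	negative	17.56	3.51e-06	2.97	B263	thymine	65-71-4
M124T65	65	124	positive	1834.90	3.82e-06	6.00	B505	picolinic acid	98-98-6
M137T63	63	137	positive	102.63	1.31e-10	4.41	B505	hypoxanthine	68-94-0
M190T192	192	190	positive	40.13	3.30e-05	3.49	B505	kynurenic acid	492-27-3
M137T84	84	137	positive	39.37	1.87e-07	3.54	B505	hypoxanthine	68-94-0
M135T84	84	135	negative	385.13	1.33e-07	4.96	B505	hypoxanthine	68-94-0
M131T125	125	131	negative	26.74	2.47e-08	2.59	B505	glutaric acid	110-94-1
M125T103	103	125	negative	18.24	2.13e-06	2.75	B505	thymine	65-71-4
M145T115	115	145	negative	12.45	2.34e-11	2.51	B505	adipic acid	124-04-9
M115T124	124	115	positive	99.99	9.33e-09	2.83	B585	ethylmalonic acid	601-75-2
M131T125	125	131	negative	233.92	6.66e-10	3.67	B585	glutaric acid	110-94-1
M145T115	115	145	negative	40.09	9.46e-13	3.14	B585	adipic acid	124-04-9
M125T103	103	125	negative	14.71	2.48e-06	2.18	B585	thymine	65-71-4
M124T226	226	124	positive	270.36	1.01e-06	4.35	B424	picolinic acid	98-98-6
M129T65	65	129	negative	35.08	2.01e-06	3.70	B424	ketoisocaproic acid	816-66-0
M129T41	41	129	negative	18.13	8.04e-05	3.36	B424	ketoisocaproic acid	816-66-0
M165T154	154	165	negative	15.91	8.20e-07	3.22	B424	phenyllactic acid	828-01-3
M165T106	106	165	negative	12.30	5.67e-12	3.08	B424	phenyllactic acid	828-01-3
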