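voi	beta	se	df	t	p	p_bonferroni
whole_brain	-12584.624	6057.012	24.7	-2.08	0.0483	1
cerebrum	-10848.905	5855.834	24.7	-1.85	0.0759	1
cerebral_gm	-6523.224	3313.096	24.7	-1.97	0.0603	1
cerebral_wm	-1610.601	1915.169	24.7	-0.841	0.408	1
cerebellum	-971.808	305.995	24.6	-3.18	0.004	0.136
cbl_lobules_1_2	1.645	1.275	24.7	1.29	0.209	1
cbl_lobule_3	5.003	7.273	24.7	0.688	0.498	1
cbl_lobule_4	-26.158	12.249	24.3	-2.14	0.043	1
cbl_lobule_5	-40.215	31.987	23.1	-1.26	0.221	1
cbl_lobule_6	-210.984	34.977	24.8	-6.03	2.75e-06	9.33e-05
cbl_crus_1	-129.373	100.688	24.4	-1.28	0.211	1
cbl_crus_2	-193.729	172.791	24.8	-1.12	0.273	1
cbl_lobule_7b	11.347	69.978	24.7	0.162	0.873	1
cbl_lobule_8a	19.061	86.51	24.6	0.22	0.827	1
cbl_lobule_8b	-18.594	46.305	24.8	-0.402	0.691	1
cbl_lobule_9	-5.616	38.073	24.1	-0.148	0.884	1
cbl_lobule_10	31.742	14.051	25	2.26	0.0328	1
cbl_wm_deep_nuclei	-308.859	46.01	24.7	-6.71	5.18e-07	1.76e-05
corpus_callosum	-46.005	11.63	24.6	-3.96	0.000569	0.0193
frontal_lobe	-5454.899	1638.349	24.9	-3.33	0.00271	0.0921
occipital_lobe	-284.578	708.166	24.6	-0.402	0.691	1
parietal_lobe	-2305.137	1287.966	24.7	-1.79	0.0858	1
temporal_lobe	1395.581	991.918	24.6	1.41	0.172	1
caudate	-106.709	25.568	24.8	-4.17	0.000321	0.0109
putamen	-141.078	24.83	24.7	-5.68	6.75e-06	0.000229
pallidum	-58.671	13.059	24.6	-4.49	0.000144	0.0049
accumbens	3.968	29.17	24.7	0.136	0.893	1
hippocampus	1.551	9.005	25	0.172	0.865	1
amygdala	-9.143	7.016	24.8	-1.3	0.204	1
thalamus	-210.56	33.103	24.9	-6.36	1.2e-06	4.07e-05
hypothalamus_plus	-89.29	30.356	24.7	-2.94	0.00699	0.238
medulla	11.577	28.214	24.3	0.41	0.685	1
pons	-304.985	31.126	25.1	-9.8	4.70e-10	1.60e-08
scp	-8.247	2.218	24.9	-3.72	0.00102	0.0348
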