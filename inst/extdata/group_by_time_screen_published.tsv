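voi	beta	se	df	t	p	p_bonferroni
whole_brain	-8417.702	6623.368	60.3	-1.27	0.209	1
cerebrum	-6864.891	6402.336	60.3	-1.07	0.288	1
cerebral_gm	-5325.858	3680.643	59.9	-1.45	0.153	1
cerebral_wm	82.611	2117.327	60.7	0.039	0.969	1
cerebellum	-1111.813	337.35	60	-3.3	0.00165	0.0562
cbl_lobules_1_2	6.182	2.126	60.3	2.91	0.00508	0.173
cbl_lobule_3	-3.674	10.721	60.2	-0.343	0.733	1
cbl_lobule_4	-14.073	19.859	60.4	-0.709	0.481	1
cbl_lobule_5	-104.775	40.724	58.8	-2.57	0.0126	0.43
cbl_lobule_6	-191.258	41.204	60.3	-4.64	1.91e-05	6.51e-04
cbl_crus_1	-212.965	121.987	60.4	-1.75	0.0859	1
cbl_crus_2	-397.944	197.379	61.9	-2.02	0.0481	1
cbl_lobule_7b	-5.103	106.154	61	-0.0481	0.962	1
cbl_lobule_8a	154.298	91.619	60.9	1.68	0.0973	1
cbl_lobule_8b	57.53	61.447	60.4	0.936	0.353	1
cbl_lobule_9	-45.321	41.75	59.4	-1.09	0.282	1
cbl_lobule_10	28.049	17.78	59.8	1.58	0.12	1
cbl_wm_deep_nuclei	-258.66	56.339	60.5	-4.59	2.28e-05	7.76e-04
corpus_callosum	-26.852	15.458	60.2	-1.74	0.0875	1
frontal_lobe	-5563.115	2729.405	60.1	-2.04	0.0459	1
occipital_lobe	521.456	740.068	60	0.705	0.484	1
parietal_lobe	-480.415	1743.822	59.8	-0.275	0.784	1
temporal_lobe	1107.655	1093.294	60.1	1.01	0.315	1
caudate	-106.223	25.915	59.8	-4.1	0.000127	0.00432
putamen	-136.797	28.651	59.2	-4.77	1.22e-05	0.000416
pallidum	-75.485	14.032	60	-5.38	1.3e-06	4.41e-05
accumbens	12.328	31.652	60.4	0.39	0.698	1
hippocampus	-4.378	11.367	58.8	-0.385	0.702	1
amygdala	-8.45	7.248	59.8	-1.17	0.248	1
thalamus	-59.833	49.289	58.8	-1.21	0.23	1
hypothalamus_plus	-78.27	41.578	60.5	-1.88	0.0646	1
medulla	-29.044	58.287	59.9	-0.498	0.62	1
pons	-348.144	40.743	59.9	-8.54	5.91e-12	2.01e-10
scp	-4.505	2.773	60.8	-1.62	0.109	1
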