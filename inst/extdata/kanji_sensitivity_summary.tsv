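session	duration_ms	mean_dprime	sd_dprime	n
1	17	0.169	0.303	27
1	50	0.581	0.511	27
1	84	0.860	0.501	27
1	117	1.529	0.709	27
1	150	1.884	0.737	27
1	234	2.364	0.634	27
1	500	2.820	0.685	27
1	1000	2.805	0.647	27
4	17	0.618	0.417	27
4	50	1.485	0.783	27
4	84	2.015	0.698	27
4	117	2.406	0.640	27
4	150	2.936	0.756	27
4	234	3.187	0.715	27
4	500	3.293	0.569	27
4	1000	3.368	0.543	27
7	17	0.694	0.471	27
7	50	1.741	0.762	27
7	84	2.388	0.685	27
7	117	2.873	0.666	27
7	150	3.166	0.518	27
7	234	3.589	0.535	27
7	500	3.379	0.364	27
7	1000	3.520	0.472	27
10	17	0.813	0.576	27
10	50	1.953	0.874	27
10	84	2.446	0.648	27
10	117	2.889	0.584	27
10	150	3.373	0.529	27
10	234	3.599	0.574	27
10	500	3.579	0.494	27
10	1000	3.491	0.467	27
11	17	0.54	0.58	16
11	50	1.75	0.77	16
11	84	2.35	1.05	16
11	117	2.90	0.72	16
11	150	2.94	0.65	16
11	234	3.04	0.53	16
11	500	3.45	0.44	16
11	1000	3.66	0.55	16
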