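no	mirna	cluster	lfc_T2	lfc_T3	lfc_T4	lfc_T5	lfc_T6	sig_T2	sig_T3	sig_T4	sig_T5	sig_T6
1	ssa-let-7b-3p	I	-1.02	-0.39	-0.52	-1.29	-0.80	TRUE	FALSE	FALSE	TRUE	FALSE
2	ssa-miR-20b-5p	I	-0.61	-0.82	-0.92	-0.98	-1.23	FALSE	FALSE	FALSE	FALSE	TRUE
3	ssa-miR-30a-3-4-3p	I	-0.37	-0.54	-0.93	-0.66	-1.05	FALSE	FALSE	FALSE	FALSE	TRUE
4	ssa-miR-125b-1-3p	I	-0.74	-1.18	-1.51	-1.38	-1.62	FALSE	TRUE	TRUE	TRUE	TRUE
5	ssa-miR-130d-2-5p	I	-0.63	-1.30	-1.30	-1.38	-1.26	FALSE	FALSE	FALSE	TRUE	TRUE
6	ssa-miR-135a-3p	I	-0.70	-0.46	-0.75	-0.77	-1.63	FALSE	FALSE	FALSE	FALSE	TRUE
7	ssa-miR-192a-5p	I	-0.87	-1.67	-4.44	-3.16	-5.24	FALSE	FALSE	TRUE	TRUE	TRUE
8	ssa-miR-194a-5p	I	-2.06	-3.01	-4.02	-3.22	-5.17	FALSE	TRUE	TRUE	TRUE	TRUE
9	ssa-miR-196a-5p	I	-0.36	-0.13	-0.89	-0.49	-1.00	FALSE	FALSE	FALSE	FALSE	TRUE
10	ssa-miR-200ae-3p	I	-0.69	-3.12	-4.40	-2.90	-5.60	FALSE	TRUE	TRUE	TRUE	TRUE
11	ssa-miR-200b-3p	I	-1.54	-2.85	-3.91	-3.89	-5.07	FALSE	TRUE	TRUE	TRUE	TRUE
12	ssa-miR-203a-3p	I	0.96	-0.85	-1.25	-0.39	-1.16	FALSE	FALSE	TRUE	FALSE	TRUE
13	ssa-miR-205b-5p	I	1.29	-0.99	-1.80	-1.46	-3.05	FALSE	FALSE	TRUE	TRUE	TRUE
14	ssa-miR-222b-5p	I	-0.90	-0.63	-0.75	-1.24	-1.00	FALSE	FALSE	FALSE	TRUE	FALSE
15	ssa-miR-301a-5p	I	-1.07	-1.59	-2.00	-2.37	-1.69	FALSE	FALSE	TRUE	TRUE	TRUE
16	ssa-miR-375-3p	I	-0.58	-0.40	-1.02	-0.07	-0.90	FALSE	FALSE	TRUE	FALSE	FALSE
17	ssa-miR-429ab-3p	I	-0.60	-1.63	-4.08	-2.48	-5.23	FALSE	FALSE	TRUE	TRUE	TRUE
18	ssa-miR-430b-5p	I	-0.84	-0.61	-1.51	-1.88	-1.71	FALSE	FALSE	TRUE	TRUE	TRUE
19	ssa-miR-449ab-5p	I	-0.82	-1.44	-2.57	-1.98	-4.44	FALSE	FALSE	TRUE	FALSE	TRUE
20	ssa-miR-722-3p	I	-0.26	-0.79	-1.61	-0.65	-1.36	FALSE	FALSE	TRUE	FALSE	TRUE
21	ssa-miR-8162-5p	I	-0.79	-0.97	-1.20	-0.99	-0.79	FALSE	FALSE	TRUE	FALSE	FALSE
22	ssa-miR-novel-2-5p	I	-1.11	-1.48	-2.35	-1.51	-2.42	FALSE	TRUE	TRUE	TRUE	TRUE
23	ssa-miR-novel-15-3p	I	-0.78	-1.32	-1.55	-0.96	-1.02	FALSE	TRUE	TRUE	FALSE	TRUE
24	ssa-miR-1-3p	II	-0.05	-1.24	0.15	-1.31	-0.99	FALSE	FALSE	FALSE	TRUE	FALSE
25	ssa-miR-15b-3p	II	-0.48	-0.22	-0.61	-1.30	-0.22	FALSE	FALSE	FALSE	TRUE	FALSE
26	ssa-miR-30a-2-3p	II	-1.11	-0.73	-0.94	-0.97	-0.85	TRUE	FALSE	FALSE	FALSE	FALSE
27	ssa-miR-92a-1-2-5p	II	-1.01	-0.21	-0.58	-0.42	-0.18	TRUE	FALSE	FALSE	FALSE	FALSE
28	ssa-miR-106b-3p	II	-0.86	-0.46	-0.97	-1.56	-0.45	FALSE	FALSE	FALSE	TRUE	FALSE
29	ssa-miR-125a-1-3p	II	-1.61	-0.37	-0.02	-0.26	-0.41	TRUE	FALSE	FALSE	FALSE	FALSE
30	ssa-miR-133-4-5p	II	-0.95	-1.26	-0.72	-1.76	-1.19	FALSE	FALSE	FALSE	FALSE	TRUE
31	ssa-miR-144-3p	II	-0.40	-0.10	0.03	-1.53	0.69	FALSE	FALSE	FALSE	TRUE	FALSE
32	ssa-miR-144-5p	II	-0.80	-0.38	-0.33	-2.35	0.42	FALSE	FALSE	FALSE	TRUE	FALSE
33	ssa-miR-301b-5p	II	-1.17	-0.65	-0.26	-1.02	-0.38	TRUE	FALSE	FALSE	TRUE	FALSE
34	ssa-miR-451-3p	II	-0.96	-1.01	-0.86	-1.68	0.27	FALSE	TRUE	FALSE	TRUE	FALSE
35	ssa-miR-730a-5p	II	-0.37	-0.11	0.10	-2.89	0.50	FALSE	FALSE	FALSE	TRUE	FALSE
36	ssa-miR-2188-3p	II	-0.30	0.37	0.68	-1.33	0.99	FALSE	FALSE	FALSE	TRUE	FALSE
37	ssa-miR-novel-12-5p	II	-0.77	-0.38	-0.69	-1.05	-0.29	FALSE	FALSE	FALSE	TRUE	FALSE
1	ssa-miR-17-1-3p	III	0.36	0.69	0.92	0.78	1.06	FALSE	FALSE	FALSE	FALSE	TRUE
2	ssa-miR-29b-1-5p	III	0.84	1.21	1.59	1.44	0.76	FALSE	TRUE	TRUE	TRUE	FALSE
3	ssa-miR-100a-2-3p	III	0.22	0.77	0.98	1.11	1.10	FALSE	FALSE	FALSE	TRUE	TRUE
4	ssa-miR-132-1-2-5p	III	0.50	0.39	0.57	1.21	0.77	FALSE	FALSE	FALSE	TRUE	FALSE
5	ssa-miR-137a-3p	III	0.34	0.23	0.80	1.01	0.84	FALSE	FALSE	FALSE	TRUE	FALSE
6	ssa-miR-146a-5p	III	0.58	0.62	0.77	1.28	1.00	FALSE	FALSE	FALSE	TRUE	TRUE
7	ssa-miR-150-3p	III	0.48	0.56	1.10	0.25	0.17	FALSE	FALSE	TRUE	FALSE	FALSE
8	ssa-miR-153a-3p	III	0.51	0.52	0.46	1.08	0.95	FALSE	FALSE	FALSE	TRUE	FALSE
9	ssa-miR-202b-5p	III	1.13	0.76	1.18	1.56	2.08	FALSE	FALSE	FALSE	FALSE	TRUE
10	ssa-miR-204-5p	III	0.35	0.51	0.72	1.27	1.01	FALSE	FALSE	FALSE	TRUE	TRUE
11	ssa-miR-216a-5p	III	1.42	0.44	0.84	0.13	0.74	TRUE	FALSE	FALSE	FALSE	FALSE
12	ssa-miR-217-5p	III	1.15	-0.35	0.44	-0.17	0.40	TRUE	FALSE	FALSE	FALSE	FALSE
13	ssa-miR-218a-5p	III	0.32	0.51	0.79	1.23	1.02	FALSE	FALSE	FALSE	TRUE	TRUE
14	ssa-miR-451-5p	III	0.44	0.51	0.71	0.27	1.01	FALSE	FALSE	FALSE	FALSE	TRUE
15	ssa-miR-725-3p	III	1.46	-0.19	-0.39	0.44	0.17	TRUE	FALSE	FALSE	FALSE	FALSE
16	ssa-miR-727a-5p	III	0.70	1.12	0.91	0.30	-0.01	FALSE	TRUE	FALSE	FALSE	FALSE
17	ssa-miR-8158-3p	III	0.58	0.52	1.02	1.27	1.25	FALSE	FALSE	TRUE	TRUE	TRUE
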