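no	gene	cluster	mirna	major_expressed
1	cxa1	I	ssa-miR-30e-3-3p	FALSE
1	cxa1	I	ssa-let-7b-3p	TRUE
1	cxa1	I	ssa-miR-194a-3p	FALSE
2	apoa1bp	I	ssa-miR-novel-15-3p	TRUE
3	star_paralog1	I	ssa-miR-30e-3-3p	FALSE
4	star_paralog2	I	ssa-miR-205b-5p	TRUE
5	fdx1l	I	ssa-miR-722-3p	TRUE
6	spink1	I	ssa-miR-196a-5p	TRUE
6	spink1	I	ssa-miR-196b-5p	FALSE
7	ptdss1	III	ssa-miR-17-1-3p	TRUE
8	agtrap	III	ssa-miR-17-1-3p	TRUE
9	gulp1	III	ssa-miR-17-1-3p	TRUE
10	spint2	III	ssa-miR-17-1-3p	TRUE
10	spint2	III	ssa-miR-217-5p	TRUE
11	grb14	III	ssa-miR-17-1-3p	TRUE
11	grb14	III	ssa-miR-204-5p	TRUE
11	grb14	III	ssa-miR-218a-5p	TRUE
12	trhde.2	III	ssa-miR-137a-3p	TRUE
12	trhde.2	III	ssa-miR-29c-5p	FALSE
13	lpl	III	ssa-miR-137a-3p	TRUE
14	epn	III	ssa-miR-137a-3p	TRUE
14	epn	III	ssa-miR-29b-3p	FALSE
14	epn	III	ssa-miR-29a-3p	FALSE
15	pnmt	III	ssa-miR-146a-5p	TRUE
15	pnmt	III	ssa-miR-146b-5p	FALSE
16	nrip2	III	ssa-miR-146a-5p	TRUE
16	nrip2	III	ssa-miR-217-5p	TRUE
16	nrip2	III	ssa-miR-725-3p	TRUE
16	nrip2	III	ssa-miR-202a-5p	FALSE
16	nrip2	III	ssa-miR-204-5p	TRUE
16	nrip2	III	ssa-miR-146b-5p	FALSE
17	nid1	III	ssa-miR-146b-5p	FALSE
18	s47a1	III	ssa-miR-146b-5p	FALSE
19	acy2	III	ssa-miR-204-5p	TRUE
20	sepp1	III	ssa-miR-204-5p	TRUE
21	itga6	III	ssa-miR-204-5p	TRUE
22	slc16a7	III	ssa-miR-204-5p	TRUE
22	slc16a7	III	ssa-miR-217-5p	TRUE
22	slc16a7	III	ssa-miR-8158-3p	TRUE
23	acy3	III	ssa-miR-204-5p	TRUE
24	rmdn2	III	ssa-miR-216a-5p	TRUE
25	cdo1	III	ssa-miR-216a-5p	TRUE
26	slc15a2	III	ssa-miR-217-5p	TRUE
27	loc106561979	III	ssa-miR-217-5p	TRUE
27	loc106561979	III	ssa-miR-727a-5p	TRUE
28	aqp8	III	ssa-miR-217-5p	TRUE
29	igfbp5	III	ssa-miR-217-5p	TRUE
30	gucy2f	III	ssa-miR-217-5p	TRUE
30	gucy2f	III	ssa-miR-725-3p	TRUE
31	gat2	III	ssa-miR-218a-5p	TRUE
32	slco1a2	III	ssa-miR-218a-5p	TRUE
32	slco1a2	III	ssa-miR-146a-3-3p	FALSE
33	gfra1	III	ssa-miR-218a-5p	TRUE
33	gfra1	III	ssa-miR-727a-5p	TRUE
34	loc106610933	III	ssa-miR-150-3p	TRUE
35	npt2a	III	ssa-miR-29c-5p	FALSE
36	prss23	III	ssa-miR-29b-3p	FALSE
36	prss23	III	ssa-miR-29a-3p	FALSE
37	cld3	III	ssa-miR-29b-3p	FALSE
37	cld3	III	ssa-miR-29a-3p	FALSE
38	pfkfb1	III	ssa-miR-725-3p	TRUE
39	sell	III	ssa-miR-725-3p	TRUE
40	cisd1	III	ssa-miR-725-3p	TRUE
41	wt1	III	ssa-miR-727a-5p	TRUE
41	wt1	III	ssa-miR-29c-5p	FALSE
42	capsl	III	ssa-miR-132-1-2-5p	TRUE
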