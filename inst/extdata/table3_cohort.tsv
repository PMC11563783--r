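patient_id	sex	age_years	phenotype	allele1	allele2	extra_copy	conv_allele1	conv_allele2	notes
1	M	0.08	SW	micro:I2G	cahx:CH2		I2G	Exon 1-10 Del	
2	M	0.17	SW	micro:I2G	novel:c.292+1G>A		I2G	c.292+1G>A	
3	M	0.08	SW	micro:p.R357W	chimera:CH1		p.R357W	Exon 1-3 Del	
4	M	0.04	SW	del:solo	cahx:CH1		Exon 1-10 Del	Exon 1-10 Del	
5	M	0.25	SW	micro:I2G	micro:I2G		I2G	I2G	
6	M	0.06	SW	novel:p.E247Gfs*11	chimera:CH2		p.E247Gfs*11	Exon 1-4 Del	
7	F	1.33	SV	micro:p.I173N	cahx:CH3		p.I173N	Exon 1-10 Del	
8	F	0.08	SV	dup:E7E8[p.V282L,p.L308Ffs*6,p.Q319X]+WT	chimera:CH4	E7E8_integration	p.L308Ffs*, p.Q319X	p.P31L	
9	M	0.05	SW	chimera:CH8	cahx:CH1		Exon 1-10 Del	Exon 1-10 Del	
10	M	0.04	SW	micro:I2G	chimera:CH3		I2G	Exon 1-7 Del	
11	M	0.08	SW	micro:I2G	cahx:CH2		I2G	Exon 1-10 Del	
12	M	0.08	SW	dup:E7E8[p.V282L,p.L308Ffs*6,p.Q319X]+WT	chimera:CH1	E7E8_integration	p.L308Ffs*, p.Q319X	Exon 1-3 Del	
13	M	5.25	SV	micro:p.I173N	chimera:CH6		p.I173N	I2G	
14	M	8.33	NC	micro:p.P31L	del:solo		p.P31L	Exon 1-10 Del	
15	F	3.08	SV	micro:I2G	chimera:CH1		I2G	Exon 1-3 Del	
16	F	0.17	SW	micro:I2G	del:solo		I2G	Exon 1-10 Del	
17	M	0.06	SW	micro:I2G	micro:p.R357W		I2G	p.R357W	
18	F	0.06	SW	micro:I2G	micro:I2G		I2G	I2G	
19	M	0.58	SW	micro:I2G	micro:I2G		I2G	I2G	
20	M	0.04	SW	micro:p.I173N	micro:p.I173N		p.I173N	p.I173N	
21	M	4.83	SV	micro:I2G	micro:p.I173N		I2G	p.I173N	
22	M	0.17	SW	micro:R357W	novel:p.R484Pfs*58		p.R357W	p.R484Pfs	
23	M	0.08	SW	micro:I2G	novel:p.S126X		I2G	p.S126X	
24	F	3.92	SV	micro:p.I173N	chimera:CH1		p.I173N	Exon 1-3 Del	
25	F	4.08	SV	micro:I2G	micro:p.I173N		I2G	p.I173N	
26	F	0.08	SV	micro:p.I173N	novel:p.V306F		p.I173N	p.V306F	
27	M	11.5	SV	micro:p.I173N	cahx:CH1		p.I173N	Exon 1-10 Del	
28	F	5.33	SV	micro:p.P31L	novel:R484Pfs*58		p.P31L	p.R484Pfs	
29	M	0.17	SW	micro:p.R357W	chimera:CH1		p.R357W	Exon 1-3 Del	
30	M	0.5	SW	micro:I2G	novel:p.G423_C424delinsVCL		I2G	p.G423_C424delinsVCL	
31	F	4.67	SV	novel:p.R484Pfs*58	micro:p.I173N		In vitro fertilization from sperm bank	p.I173N	phase_unavailable:1
32	M	0.05	SW	micro:p.Q319X	cahx:CH1		p.Q319X	Exon 1-10 Del	
33	F	2.91	SV	micro:I2G	micro:p.I173N		I2G	p.I173N	
34	M	3.33	SW	micro:p.I173N	novel:c.292+1G>A		p.I173N	c.292 + 1G > A	
35	M	0.17	SW	micro:I2G	novel:p.R355H		I2G	p.R355H	
36	M	0.07	SV	micro:I2G	micro:p.I173N		I2G	p.I173N	
37	F	3.17	SV	micro:p.G111Vfs*21	micro:p.I173N		p.G111Vfs*21	p.I173N	
38	M	0.08	SW	micro:I2G	novel:p.S126X		I2G	p.S126X	
39	M	0.32	SW	micro:p.I173N	novel:p.R484Pfs*58		p.I173N	p.R484Pfs	
40	M	0.08	SW	micro:I2G+p.G111Vfs*21	micro:I2G		I2G, p.G111Vfs*21	I2G	
41	M	3.66	SV	micro:p.I173N	novel:c.292+1G>A		p.I173N	c.292 + 1G > A	
42	F	0.17	SW	micro:I2G	micro:p.I173N		I2G	p.I173N	
43	M	0.17	SW	micro:I2G	micro:p.R357W		I2G	p.R357W	
44	F	2.42	SV	micro:p.I173N	micro:p.Q319X		p.I173N	p.Q319X	
45	F	1.17	NC	chimera:CH4	dup:E7E8[p.L308Ffs*6,p.Q319X]		p.P31L	p.L308Ffs*6, p.Q319X	
46	F	3.83	NC	chimera:CH4	dup:E7E8[p.L308Ffs*6,p.Q319X]		p.P31L	p.L308Ffs*6, p.Q319X	
47	M	0.03	SW	micro:p.Q319X	micro:p.R357W		p.Q319X	p.R357W	
48	M	0.04	SW	micro:I2G	micro:I2G		I2G	I2G	
49	F	6.17	SV	micro:I2G	cahx:CH1		I2G	Exon 1-10 Del	
50	F	0.08	SV	micro:p.I173N	micro:p.I173N		p.I173N	p.I173N	
51	F	0.08	SW	cahx:CH1	cahx:CH1		Exon 1-10 Del	Exon 1-10 Del	
52	M	3.67	SV	micro:p.I173N	novel:p.S126X		p.I173N	p.S126X	
53	M	0.32	SW	micro:I2G	cahx:CH1		I2G	Exon 1-10 Del	
54	M	0.17	SW	micro:I2G	novel:p.R484Pfs*58		I2G	p.R484Pfs	
55	F	0.01	SV	micro:p.Q319X	micro:p.R357W		p.Q319X	p.R357W	
56	M	0.17	SV	micro:E6cluster	micro:p.R357W		E6cluster	p.R357W	
57	F	0.02	SW	micro:I2G	cahx:CH1		I2G	Exon 1-10 Del	
58	M	0.65	SW	micro:UTR5+p.Q319X	micro:p.R357W		p.Q319X	negative	missed_point_call:2
59	M	0.05	SW	chimera:CH1	cahx:CH1		Exon 1-3 Del	Exon 1-10 Del	recorded_concordant:1
60	M	4.25	SV	micro:I2G	micro:p.I173N		I2G	p.I173N	
61	M	6.58	NC	micro:p.P31L	micro:E6cluster		p.P31L	E6cluster	
62	M	0.15	NC	micro:p.P31L	cahx:CH1		p.P31L	Exon 1-10 Del	
63	M	6.67	SV	micro:I2G	micro:p.I173N		I2G	p.I173N	
64	M	0.12	SW	micro:I2G	micro:Q319X		I2G	p.Q319X	
65	F	7.33	SV	micro:I2G	novel:R484Q		I2G	p.R484Q	
66	M	0.23	SW	micro:I2G	novel:R484Pfs*58		I2G	p.R484Pfs	
67	F	0.17	SW	micro:I2G	micro:R357W		I2G	R357W	
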