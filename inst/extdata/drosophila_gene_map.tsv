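column	compartment	symbol
1	1	SLP
2	1	wg
3	1	WG
4	1	en
5	1	EN
6	1	hh
7	1	HH
8	1	ptc
9	1	PTC
10	1	PH
11	1	SMO
12	1	ci
13	1	CI
14	1	CIA
15	1	CIR
16	2	SLP
17	2	wg
18	2	WG
19	2	en
20	2	EN
21	2	hh
22	2	HH
23	2	ptc
24	2	PTC
25	2	PH
26	2	SMO
27	2	ci
28	2	CI
29	2	CIA
30	2	CIR
31	3	SLP
32	3	wg
33	3	WG
34	3	en
35	3	EN
36	3	hh
37	3	HH
38	3	ptc
39	3	PTC
40	3	PH
41	3	SMO
42	3	ci
43	3	CI
44	3	CIA
45	3	CIR
46	4	SLP
47	4	wg
48	4	WG
49	4	en
50	4	EN
51	4	hh
52	4	HH
53	4	ptc
54	4	PTC
55	4	PH
56	4	SMO
57	4	ci
58	4	CI
59	4	CIA
60	4	CIR
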