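index	kind	k	ordered	included
1	qualitative	2	0	1
2	quantitative	2	0	1
3	quantitative	2	0	1
4	quantitative	2	0	1
5	qualitative	2	0	1
6	qualitative	2	1	1
7	quantitative	2	0	1
8	qualitative	3	0	1
9	qualitative	3	1	0
10	qualitative	3	0	1
11	qualitative	2	0	1
12	quantitative	2	0	1
13	qualitative	2	0	1
14	qualitative	2	0	1
15	qualitative	2	0	1
16	qualitative	2	0	1
17	qualitative	2	0	1
18	quantitative	2	0	1
19	qualitative	5	0	1
20	qualitative	4	0	1
21	qualitative	2	0	1
22	qualitative	2	1	1
23	qualitative	2	0	1
24	qualitative	2	0	1
25	qualitative	3	0	1
26	qualitative	2	0	1
27	qualitative	3	1	1
28	qualitative	3	0	1
29	qualitative	3	1	1
30	qualitative	2	0	1
31	qualitative	4	0	1
32	qualitative	3	0	1
33	qualitative	2	0	1
34	qualitative	2	0	0
35	qualitative	3	0	1
36	qualitative	2	0	1
37	qualitative	3	1	1
38	qualitative	2	0	1
39	qualitative	2	0	1
40	quantitative	2	0	1
41	quantitative	2	0	1
42	quantitative	2	0	1
43	quantitative	2	0	1
44	qualitative	2	1	1
45	qualitative	2	0	1
46	qualitative	2	0	0
47	qualitative	3	0	1
48	qualitative	3	0	1
49	qualitative	2	0	1
50	qualitative	4	0	1
51	qualitative	4	0	1
52	qualitative	5	0	1
53	qualitative	2	0	1
54	qualitative	2	0	1
55	qualitative	2	0	1
56	qualitative	2	0	1
57	qualitative	3	0	1
58	quantitative	2	0	1
59	qualitative	2	0	1
60	qualitative	3	1	1
61	quantitative	2	0	1
62	quantitative	2	0	1
63	qualitative	2	0	1
64	qualitative	2	0	1
65	qualitative	3	0	1
66	qualitative	2	0	1
67	qualitative	2	0	1
68	qualitative	2	0	1
69	qualitative	2	0	1
70	qualitative	2	0	1
71	qualitative	2	0	1
72	qualitative	2	0	1
73	qualitative	2	0	1
74	qualitative	2	0	1
75	qualitative	2	0	1
76	qualitative	2	0	1
77	quantitative	2	0	1
78	quantitative	2	0	1
79	qualitative	3	0	1
80	qualitative	2	0	1
81	qualitative	2	0	1
82	qualitative	2	0	1
83	qualitative	2	0	1
84	qualitative	2	0	1
85	qualitative	3	1	1
86	qualitative	2	0	1
87	qualitative	2	0	1
88	quantitative	2	0	1
89	qualitative	2	0	1
90	qualitative	2	0	1
91	qualitative	2	0	1
92	qualitative	2	0	1
93	quantitative	2	0	1
94	qualitative	5	0	1
95	qualitative	2	0	1
96	qualitative	3	0	1
97	qualitative	2	0	1
98	qualitative	2	0	1
99	qualitative	2	0	1
100	qualitative	2	0	1
101	qualitative	2	0	1
102	qualitative	6	0	1
103	qualitative	2	0	1
104	qualitative	2	0	1
105	qualitative	2	0	1
106	quantitative	2	0	1
107	qualitative	2	0	1
108	qualitative	3	0	1
109	qualitative	2	0	1
110	qualitative	3	0	1
111	quantitative	2	0	1
112	quantitative	2	0	1
113	quantitative	2	0	1
114	quantitative	2	0	1
115	quantitative	2	0	1
116	quantitative	2	0	1
117	qualitative	3	0	1
118	qualitative	2	0	1
119	qualitative	4	0	1
120	qualitative	2	0	1
121	qualitative	2	0	1
122	qualitative	2	0	1
123	qualitative	4	1	1
124	qualitative	3	0	1
125	qualitative	2	0	1
126	qualitative	3	0	1
127	qualitative	2	0	1
128	qualitative	2	0	1
129	qualitative	2	0	1
130	qualitative	2	0	1
131	quantitative	2	0	1
132	qualitative	2	0	1
133	qualitative	3	1	1
134	qualitative	3	0	1
135	qualitative	2	0	1
136	qualitative	2	0	1
137	qualitative	2	0	1
138	qualitative	2	0	1
139	qualitative	3	0	1
140	qualitative	2	0	1
141	qualitative	2	0	1
142	qualitative	3	0	1
143	qualitative	2	0	1
144	qualitative	2	0	1
145	qualitative	3	1	1
146	qualitative	2	0	1
147	qualitative	2	0	1
148	qualitative	2	0	1
149	qualitative	2	0	1
150	qualitative	2	0	1
151	quantitative	2	0	1
152	qualitative	3	0	1
153	qualitative	2	0	1
154	qualitative	4	0	1
155	qualitative	2	0	1
156	quantitative	2	0	1
157	qualitative	2	0	1
158	qualitative	3	0	1
159	qualitative	2	0	1
160	qualitative	2	0	1
161	qualitative	3	1	1
162	qualitative	2	0	0
163	qualitative	2	0	1
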