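position	pocket
59	A
62	A
63	A
65	A
66	A
69	B
70	B
73	B
74	B
77	C
80	C
81	C
84	C
88	C
91	C
95	C
97	C
99	D
114	D
116	D
122	D
123	D
143	E
146	E
147	E
152	E
161	F
170	F
180	F
181	F
186	F
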