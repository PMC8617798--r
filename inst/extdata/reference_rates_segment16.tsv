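person	knn	nb	rf	svm
1	0.92	1.0	1.0	0.92
2	0.85	1.0	1.0	0.69
3	0.62	0.23	0.31	0.0
4	0.0	0.38	0.62	0.0
5	1.0	1.0	1.0	0.23
6	0.62	0.0	0.31	0.38
7	0.54	0.69	0.46	0.31
8	1.0	1.0	1.0	1.0
9	1.0	1.0	1.0	1.0
10	0.62	1.0	1.0	0.92
11	0.62	1.0	1.0	0.08
12	0.0	1.0	1.0	1.0
13	0.62	1.0	1.0	0.77
14	1.0	1.0	1.0	1.0
15	1.0	1.0	1.0	1.0
16	1.0	1.0	1.0	1.0
17	1.0	0.62	0.92	0.31
18	1.0	1.0	1.0	1.0
19	0.0	1.0	1.0	1.0
20	0.0	0.08	0.38	0.15
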