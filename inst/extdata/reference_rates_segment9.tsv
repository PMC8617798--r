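person	knn	nb	rf	svm
1	1.0	0.92	1.0	0.69
2	1.0	1.0	1.0	0.0
3	1.0	0.92	1.0	0.85
4	0.23	1.0	1.0	0.0
5	1.0	1.0	1.0	0.0
6	0.92	0.92	0.69	0.0
7	1.0	1.0	1.0	0.08
8	0.38	0.54	0.77	0.54
9	0.0	0.23	0.15	0.0
10	0.92	0.92	0.85	0.08
11	0.46	1.0	1.0	1.0
12	0.85	0.85	0.92	0.15
13	0.0	0.85	0.54	0.0
14	0.0	0.77	0.92	0.92
15	0.77	0.69	0.38	0.31
16	1.0	0.77	0.85	1.0
17	1.0	0.92	0.38	1.0
18	1.0	1.0	1.0	1.0
19	0.15	0.46	1.0	1.0
20	0.31	0.0	0.0	1.0
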