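k	start_ms	end_ms	knn	nb	rf	svm
1	-100	-50	0.4	0.35	0.15	0.4
2	-50	0	0.55	0.45	0.45	0.2
3	0	50	0.35	0.4	0.3	0.45
4	50	100	0.35	0.65	0.35	0.4
5	100	150	0.4	0.65	0.55	0.4
6	150	200	0.5	0.5	0.2	0.35
7	200	250	0.55	0.5	0.5	0.35
8	250	300	0.55	0.35	0.55	0.55
9	300	350	0.65	0.8	0.75	0.5
10	350	400	0.5	0.6	0.7	0.45
11	400	450	0.7	0.65	0.55	0.5
12	450	500	0.55	0.75	0.5	0.55
13	500	550	0.6	0.6	0.5	0.7
14	550	600	0.5	0.65	0.55	0.75
15	600	650	0.6	0.7	0.75	0.6
16	650	700	0.65	0.8	0.85	0.65
17	700	750	0.65	0.7	0.45	0.45
18	750	800	0.5	0.5	0.55	0.15
19	800	850	0.25	0.4	0.3	0.25
20	850	900	0.4	0.55	0.5	0.5
21	900	950	0.5	0.6	0.2	0.8
22	950	1000	0.65	0.7	0.5	0.65
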