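variant	pdb_id	template	resolution	mutations	t_m	t_i	t_50	rc_median	rc_median_K	rc_median_avg	rc_median_avg_K	source
WT	1ISP	NA	1.3	-	329.15	324.95	321.15	-0.87	317.4	-0.80	315.9	wild_type
IX	NA	1ISP	NA	K112D, M134D, Y139C, I157M	NA	318.75	335.95	-0.67	313.5	NA	NA	reetz
X	NA	1ISP	NA	R33Q, D34N, K35D, K112D, M134D, Y139C, I157M	NA	321.65	362.15	-0.73	314.5	NA	NA	reetz
XI	NA	1ISP	NA	R33G, K112D, M134D, Y139C, I157M	NA	322.45	366.15	-0.74	314.9	NA	NA	reetz
TM	1T2N	NA	1.8	L114P, A132D, N166Y	334.35	NA	NA	-0.88	317.6	NA	NA	rao
1-14F5	NA	1T2N	NA	TM + N89Y	336.15	NA	NA	-0.98	319.5	NA	NA	rao
1-17A4	3D2A	NA	1.73	TM + I157M	336.55	NA	NA	-1.00	319.9	NA	NA	rao
1-8D5	NA	1T2N	NA	TM + F17S	337.55	NA	NA	-0.81	316.3	NA	NA	rao
2D9	3D2B	NA	1.95	TM + F17S, N89Y, I157M	340.55	NA	NA	-0.98	319.7	NA	NA	rao
3-18G4	NA	3D2B	NA	2D9 + G111D	341.55	NA	NA	-0.92	318.5	NA	NA	rao
3-11G1	NA	3D2B	NA	2D9 + A20E	341.75	NA	NA	-0.98	319.6	NA	NA	rao
3-3A9	NA	3D2B	NA	2D9 + A15S	341.85	NA	NA	-0.87	317.5	NA	NA	rao
4D3	3D2C	NA	2.18	2D9 + A15S, A20E, G111D	344.35	NA	NA	-1.18	323.6	NA	NA	rao
5-D	NA	3D2C	NA	4D3 + S163P	345.35	NA	NA	-1.00	320.0	NA	NA	rao
5-A	NA	3D2C	NA	4D3 + M134E	346.05	NA	NA	-0.97	319.4	NA	NA	rao
5-B	NA	3D2C	NA	4D3 + M137P	347.25	NA	NA	-1.03	320.5	NA	NA	rao
6B	3QMM	NA	1.89	4D3 + M134E, M137P, S163P	351.35	NA	NA	-1.20	324.0	NA	NA	rao
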