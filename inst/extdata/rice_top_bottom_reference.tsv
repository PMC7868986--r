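predictor	trait	top_mean	top_sd	bottom_mean	bottom_sd
G	YIELD	47.61	0.39	39.24	0.50
T	YIELD	49.67	0.87	37.63	0.21
M	YIELD	49.91	0.65	37.06	0.56
GT	YIELD	49.18	1.17	37.83	0.25
GM	YIELD	49.46	0.70	37.16	0.47
TM	YIELD	49.99	0.57	37.26	0.46
GTM	YIELD	49.46	0.70	37.16	0.47
GP	YIELD	52.58	1.21	35.11	0.76
TP	YIELD	54.69	1.68	33.67	0.93
MP	YIELD	54.91	1.81	33.39	1.04
GTP	YIELD	51.94	1.11	35.50	0.74
GMP	YIELD	51.86	1.15	35.42	0.79
TMP	YIELD	55.36	1.88	33.11	1.04
GTMP	YIELD	51.86	1.15	35.42	0.79
G	TILLER	17.25	0.11	13.94	0.09
T	TILLER	17.30	0.12	13.61	0.20
M	TILLER	17.31	0.19	13.83	0.14
GT	TILLER	17.34	0.18	13.61	0.16
GM	TILLER	17.37	0.13	13.91	0.09
TM	TILLER	17.35	0.14	13.62	0.19
GTM	TILLER	17.38	0.15	13.63	0.14
GP	TILLER	17.97	0.25	12.99	0.36
TP	TILLER	18.18	0.25	12.95	0.27
MP	TILLER	17.92	0.24	13.04	0.33
GTP	TILLER	18.18	0.25	12.92	0.27
GMP	TILLER	17.95	0.25	12.98	0.34
TMP	TILLER	18.16	0.25	12.97	0.27
GTMP	TILLER	18.16	0.25	12.92	0.27
G	GRAIN	135.19	1.65	95.81	1.50
T	GRAIN	138.81	0.65	92.20	2.17
M	GRAIN	139.38	1.82	89.22	2.90
GT	GRAIN	137.39	0.79	91.82	1.77
GM	GRAIN	137.19	1.48	90.77	2.01
TM	GRAIN	139.36	1.73	90.02	3.01
GTM	GRAIN	137.58	1.49	90.87	2.26
GP	GRAIN	152.82	5.32	80.42	3.12
TP	GRAIN	156.29	5.89	77.43	3.84
MP	GRAIN	158.77	6.61	76.38	3.77
GTP	GRAIN	152.11	4.96	80.47	3.45
GMP	GRAIN	154.32	5.61	79.50	3.35
TMP	GRAIN	156.13	5.79	77.91	3.81
GTMP	GRAIN	152.93	5.07	80.18	3.54
G	KGW	27.79	0.15	22.49	0.21
T	KGW	27.60	0.10	22.19	0.13
M	KGW	27.93	0.27	22.09	0.28
GT	KGW	27.80	0.18	22.22	0.21
GM	KGW	27.59	0.14	22.30	0.22
TM	KGW	27.63	0.16	22.11	0.23
GTM	KGW	27.67	0.16	22.19	0.22
GP	KGW	29.20	0.41	20.72	0.48
TP	KGW	29.20	0.41	20.80	0.46
MP	KGW	29.15	0.42	20.84	0.47
GTP	KGW	29.30	0.42	20.63	0.48
GMP	KGW	29.32	0.43	20.59	0.50
TMP	KGW	29.17	0.41	20.83	0.46
GTMP	KGW	29.26	0.42	20.69	0.48
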