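structure	site	species	overlap	delta_nmr	delta_dft	delta_xrd
Para	1(OH)	1H	FALSE	9.2	9.79	9.32
Para	H2	1H	FALSE	5.75	5.42	5.31
Para	H3	1H	TRUE	6.6	6.76	6.67
Para	H5	1H	FALSE	7.86	7.95	7.90
Para	H6	1H	TRUE	6.6	6.58	6.48
Para	NH	1H	FALSE	9.03	9.47	9.06
Para	CH3	1H	FALSE	1.07	0.68	0.20
Para	C1	13C	FALSE	152.18	154.21	154.06
Para	C2	13C	FALSE	116.19	116.56	115.82
Para	C3	13C	FALSE	120.48	121.49	121.66
Para	C4	13C	FALSE	132.91	133.33	134.26
Para	C5	13C	FALSE	123.24	124.62	124.36
Para	C6	13C	FALSE	115.64	115.82	115.78
Para	CO	13C	FALSE	169.69	166.50	165.97
Para	CH3	13C	FALSE	23.64	21.43	18.07
ParaHCl	1(OH)	1H	FALSE	8.2	8.33	-0.99
ParaHCl	H2	1H	TRUE	6.5	6.58	4.24
ParaHCl	H3	1H	FALSE	6.7	6.62	5.00
ParaHCl	H5	1H	TRUE	6.5	6.46	4.01
ParaHCl	H6	1H	FALSE	6.2	6.17	3.36
ParaHCl	COH+	1H	FALSE	16.91	17.22	10.86
ParaHCl	NH	1H	FALSE	10.76	10.39	4.24
ParaHCl	CH3	1H	FALSE	2.82	2.56	-1.84
ParaHCl	H2AO	1H	FALSE	7.2	7.21	-2.23
ParaHCl	H2BO	1H	FALSE	6.6	6.58	-0.97
ParaHCl	C1	13C	FALSE	155.79	157.66	157.55
ParaHCl	C2	13C	FALSE	114.66	113.92	107.11
ParaHCl	C3	13C	TRUE	122.23	123.12	117.79
ParaHCl	C4	13C	FALSE	128.22	128.85	128.03
ParaHCl	C5	13C	TRUE	122.23	122.17	116.03
ParaHCl	C6	13C	FALSE	117.54	118.07	113.47
ParaHCl	COH+	13C	FALSE	172.43	168.37	169.89
ParaHCl	CH3	13C	FALSE	22.63	19.62	-2.00
ParaOA	1(OH)	1H	FALSE	8.3	9.23	8.92
ParaOA	H2	1H	FALSE	5.5	5.54	5.31
ParaOA	H3	1H	FALSE	6.5	6.66	6.42
ParaOA	H5	1H	TRUE	7.2	7.39	7.37
ParaOA	H6	1H	TRUE	7.2	7.18	6.85
ParaOA	NH	1H	FALSE	9.3	10.17	10.00
ParaOA	CH3	1H	FALSE	1.99	1.78	1.46
ParaOA	HOA1	1H	FALSE	11.68	12.57	11.06
ParaOA	HOAN	1H	FALSE	14.75	16.39	13.62
ParaOA	C1	13C	FALSE	150.78	154.60	152.61
ParaOA	C2	13C	TRUE	115.05	115.41	110.81
ParaOA	C3	13C	TRUE	120.86	122.50	121.49
ParaOA	C4	13C	FALSE	132.77	133.74	134.02
ParaOA	C5	13C	TRUE	120.86	123.26	123.06
ParaOA	C6	13C	TRUE	115.05	115.03	117.34
ParaOA	CO	13C	FALSE	173.84	173.32	171.12
ParaOA	CH3	13C	FALSE	24.27	21.80	19.92
ParaOA	COA1	13C	FALSE	160.38	162.79	162.01
ParaOA	COAN	13C	FALSE	159.43	161.47	158.85
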