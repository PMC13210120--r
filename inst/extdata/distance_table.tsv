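structure	site_j	site_k	f_nmr	f_dft	f_xrd	reff_dft	reff_nmr_dft	delta_dft	reff_xrd	reff_nmr_xrd	delta_xrd	excluded	motion
Para	1(OH),NH	H2	0.029	0.024	0.021	229	220	9	230	218	12	FALSE	static
Para	1(OH),NH	H3,H6	0.071	0.061	0.057	235	227	8	235	226	9	FALSE	static
Para	1(OH),NH	CH3	0.074	0.067	0.060	193	188	5	194	187	7	FALSE	static
Para	H2	H3,H6	0.034	0.019	0.018	237	214	23	236	213	23	FALSE	static
Para	H2	CH3	0.056	0.051	0.043	202	197	5	205	196	9	FALSE	static
Para	H3,H6	H5	0.022	0.022	0.020	232	230	2	233	229	4	FALSE	static
Para	H3,H6	CH3	0.065	0.039	0.035	211	192	19	211	191	20	FALSE	static
Para	H5	H5	0.026	0.030	0.026	221	224	-3	222	222	0	FALSE	static
Para	H5	CH3	0.012	0.012	0.011	290	287	3	290	285	5	FALSE	static
Para	CH3	CH3	0.611	0.675	0.709	177	178	-1	173	177	-4	FALSE	static
ParaHCl	1-6,H2O	1-6,H2O	0.424	0.506	0.632	164	169	-5	144	154	-10	FALSE	static
ParaHCl	1-6,H2O	COH+	0.085	0.141	0.078	203	221	-18	205	202	3	FALSE	static
ParaHCl	1-6,H2O	NH	0.113	0.054	0.033	213	188	25	211	172	39	FALSE	static
ParaHCl	1-6,H2O	CH3	0.122	0.098	0.055	260	251	9	260	228	32	FALSE	static
ParaHCl	COH+	NH	0.010	0.005	0.003	318	301	17	315	273	42	FALSE	static
ParaHCl	COH+	CH3	0.032	0.039	0.026	225	236	-11	219	214	5	FALSE	static
ParaHCl	NH	CH3	0.055	0.050	0.030	216	212	4	213	193	20	FALSE	static
ParaHCl	CH3	CH3	0.159	0.107	0.143	181	170	11	157	154	3	FALSE	fast_3site
ParaOA	1-6,NH	1-6,NH	0.458	0.384	0.404	230	223	7	222	218	4	FALSE	static
ParaOA	H5,H6,NH	CH3	0.386	0.578	0.564	NA	NA	NA	NA	NA	NA	TRUE	static
ParaOA	H5,H6	HOAN	0.035	0.047	0.044	314	330	-16	305	317	-12	FALSE	static
ParaOA	CH3	CH3	0.295	0.274	0.294	177	175	2	168	168	0	FALSE	fast_3site
ParaOA	CH3	HOA1	0.010	0.017	0.020	332	364	-32	314	354	-40	FALSE	static
ParaOA	CH3	HOAN	0.063	0.112	0.094	242	266	-24	242	259	-17	FALSE	static
ParaOA	HOA1	1(OH)	0.080	0.099	0.065	220	228	-8	227	219	8	FALSE	static
ParaOA	HOA1	H2	0.049	0.054	0.057	243	247	-4	232	238	-6	FALSE	static
ParaOA	HOA1	HOAN	0.010	0.013	0.022	309	321	-12	276	312	-36	FALSE	static
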