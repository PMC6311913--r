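dinucleotide	enthalpy	enthalpy2	entropy	entropy2	free_energy	free_energy2	hydrophilicity	hydrophilicity2	rise	roll	shift	slide	stacking_energy	tilt	twist
AA	-6.82	-6.6	-19.0	-18.4	-0.93	-0.9	0.023	0.04	3.18	7.0	-0.08	-1.27	-13.7	-0.8	31.0
AC	-11.40	-10.2	-29.5	-26.2	-2.24	-2.1	0.083	0.14	3.24	4.8	0.23	-1.43	-13.8	0.8	32.0
AG	-10.48	-7.6	-27.1	-19.2	-2.08	-1.7	0.035	0.08	3.30	8.5	-0.04	-1.50	-14.0	0.5	30.5
AU	-9.38	-5.7	-26.7	-15.5	-1.10	-0.9	0.090	0.14	3.24	4.4	-0.06	-1.36	-15.4	1.1	33.0
CA	-10.44	-10.5	-26.9	-27.8	-2.11	-1.8	0.118	0.21	3.45	9.9	0.11	-1.46	-14.4	1.0	31.5
CC	-13.39	-12.2	-32.7	-29.7	-3.26	-2.9	0.349	0.49	3.36	8.7	-0.01	-1.78	-11.1	0.3	32.5
CG	-10.64	-8.0	-26.7	-19.4	-2.36	-2.0	0.193	0.35	3.33	12.1	0.30	-1.89	-15.6	-0.1	29.8
CU	-10.48	-7.6	-27.1	-19.2	-2.08	-1.7	0.378	0.52	3.30	8.5	-0.04	-1.50	-14.0	0.5	30.5
GA	-12.44	-13.3	-32.5	-35.5	-2.35	-2.3	0.048	0.10	3.38	9.4	0.07	-1.70	-14.2	1.3	32.2
GC	-14.88	-14.2	-36.9	-34.9	-3.42	-3.4	0.146	0.26	3.22	6.1	0.07	-1.39	-16.9	0.0	34.0
GG	-13.39	-12.2	-32.7	-29.7	-3.26	-2.9	0.065	0.17	3.36	8.7	-0.01	-1.78	-11.1	0.3	32.5
GU	-11.40	-10.2	-29.5	-26.2	-2.24	-2.1	0.160	0.27	3.24	4.8	0.23	-1.43	-13.8	0.8	32.0
UA	-7.69	-8.1	-20.5	-22.6	-1.33	-1.1	0.112	0.21	3.26	10.7	-0.02	-1.45	-16.0	-0.2	32.8
UC	-12.44	-13.3	-32.5	-35.5	-2.35	-2.3	0.359	0.48	3.38	9.4	0.07	-1.70	-14.2	1.3	32.2
UG	-10.44	-10.5	-26.9	-27.8	-2.11	-1.8	0.224	0.34	3.45	9.9	0.11	-1.46	-14.4	1.0	31.5
UU	-6.82	-6.6	-19.0	-18.4	-0.93	-0.9	0.389	0.44	3.18	7.0	-0.08	-1.27	-13.7	-0.8	31.0
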