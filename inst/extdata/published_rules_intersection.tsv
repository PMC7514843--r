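NR	A1	A2	A3	A4	Co	S	Pr
2	F_T = 1	SP_IN = 1	VEH_TY = 1	DR_INFR = 5	FI	0.1033%	68.8%
3	WE_CO = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.23%	59.5%
4	RO_SU = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.2166%	58.03%
5	MAN = 1	PAV = 0	SP_IN = 1	ACT_TY = 2	FI	0.1466%	57.89%
6	RO_SU = 1	ACT_TY = 5	DR_INFR = 5	MAN = 1	FI	0.1166%	57.38%
7	DR_INFR = 5	SP_IN = 1	ACT_TY = 2		FI	0.2432%	57.03%
8	I_L = 1	DR_INFR = 5	SP_IN = 1	ACT_TY = 2	FI	0.2266%	56.66%
9	LUM = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.1733%	56.52%
10	I_T = 2	DR_INFR = 1	MAN = 8	O_L = 1	FI	0.1033%	56.36%
11	SP_IN = 1	DR_INFR = 5	ACT_TY = 2	RES_VIS = 1	FI	0.2%	55.55%
12	MAN = 8	SP_IN = 1	DR_INFR = 1		FI	0.166%	50.5%
13	ACT_TY = 2	DR_INFR = 1	SP_IN = 1	SEX = 1	FI	0.17%	46.79%
14	AG_FR = 2	PAV = 0	SP_IN = 1	ACT_TY = 2	FI	0.16%	46.6%
15	VEH_TY = 1	ACT_TY = 2	MAN = 1	SP_IN = 1	FI	0.2%	44.03%
16	LUM = 1	PAV = 0	SP_IN = 1	ACT_TY = 2	FI	0.33%	38.17%
17	AN = 1	PAV = 0	SP_IN = 1	ACT_TY = 2	FI	0.45%	37.6%
18	WE_CO = 1	PAV = 0	SP_IN = 1	ACT_TY = 2	FI	0.423%	37.02%
19	F_T = 3	PAV = 0	ACT_TY = 2	SP_IN = 1	FI	0.1766%	36.8%
20	RES_VIS = 1	PAV = 0	ACT_TY = 2	SP_IN = 1	FI	0.397%	34.9%
21	AG_FR = 3	PAV = 0	SP_IN = 1	ACT_TY = 2	FI	0.1866%	32.75%
22	AG_FR = 2	ACT_TY = 2	SP_IN = 1	I_T = 2	FI	0.11%	31.73%
23	SEX = 1	DR_INFR = 1	ACT_TY = 1	PR = 1	FI	0.213%	17.2%
24	RO_SU = 1	ACT_TY = 1	DR_INFR = 1	PR = 1	FI	0.29%	16.86%
25	PR = 1	DR_INFR = 1	LUM = 1		FI	0.24%	16.78%
26	WE_CO = 1	ACT_TY = 1	DR_INFR = 1	PR = 1	FI	0.29%	16.6%
27	AN = 1	ACT_TY = 1	DR_INFR = 1	PR = 1	FI	0.296%	16.45%
28	ACT_TY = 1	DR_INFR = 1	PR = 1		FI	0.296%	16.42%
29	PAV = 0	DR_INFR = 1	ACT_TY = 1	PR = 1	FI	0.296%	16.42%
30	S_W = 3	ACT_TY = 1	DR_INFR = 1	PR = 1	FI	0.11%	14.86%
31	RES_VIS = 1	ACT_TY = 1	DR_INFR = 1	PR = 1	FI	0.246%	14.77%
32	LUM = 1	ACT_TY = 1	DR_INFR = 1	PR = 1	FI	0.183%	14.66%
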