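NR	A1	A2	A3	A4	Co	S	Pr
1	SP_IN = 1	ACT_TY = 2	DR_INFR = 5	MAN = 8	FI	0.117%	71.11%
2	S_W = 3	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.314%	64.18%
3	F_T = 4	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.245%	62.03%
4	TR_N_INT = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.574%	59.25%
5	LUM = 3	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.179%	59.03%
6	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	RO_SU = 1	FI	0.56%	58.85%
7	MAN = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.38%	58.76%
8	SEX = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.46%	58.6%
9	AN = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.59%	58.06%
10	DR_INFR = 5	ACT_TY = 2	SP_IN = 1	O_L = 1	FI	0.49%	58%
11	LUM = 1	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.377%	57.54%
12	I_L = 1	DR_INFR = 5	ACT_TY = 2	SP_IN = 1	FI	0.56%	57.52%
13	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	RES_VIS = 1	FI	0.5%	56.61%
14	VEH_TY = 2	ACT_TY = 2	DR_INFR = 5	SP_IN = 1	FI	0.465%	55.95%
15	ACT_TY = 2	SP_IN = 1	DR_INFR = 1	PAV = 0	FI	0.135%	54.41%
16	VEH_TY = 1	SP_IN = 1	DR_INFR = 5	F_T = 1	FI	0.113%	53.45%
17	S_W = 1	ACT_TY = 2	SP_IN = 1	PAV = 0	FI	0.143%	43.82%
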