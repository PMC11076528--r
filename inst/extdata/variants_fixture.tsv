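sample_id	chromosome	position	ref	alt	depth	vaf	gene	expect_clocklike	expect_quality
VS1	1	1000	C	T	50	0.1		TRUE	TRUE
VS1	1	2000	T	C	50	0.1		TRUE	TRUE
VS1	1	3000	G	A	50	0.1		TRUE	TRUE
VS1	1	4000	A	G	50	0.1		TRUE	TRUE
VS1	1	5000	C	A	50	0.1		FALSE	TRUE
VS1	1	6000	C	G	50	0.1		FALSE	TRUE
VS1	1	7000	T	A	50	0.1		FALSE	TRUE
VS1	1	8000	T	G	50	0.1		FALSE	TRUE
VS1	1	9000	G	C	50	0.1		FALSE	TRUE
VS1	1	10000	G	T	50	0.1		FALSE	TRUE
VS1	1	11000	A	C	50	0.1		FALSE	TRUE
VS1	1	12000	A	T	50	0.1		FALSE	TRUE
VS1	1	13000	C	T	24	0.1		TRUE	FALSE
VS1	1	14000	C	T	25	0.1		TRUE	TRUE
VS1	1	15000	C	T	100	0.1		TRUE	TRUE
VS1	1	16000	C	T	101	0.1		TRUE	FALSE
VS1	1	17000	C	T	50	0.35		TRUE	TRUE
VS1	1	18000	C	T	50	0.36		TRUE	FALSE
VS1	1	19000	C	T	50	0.5		TRUE	FALSE
VS1	1	20000	C	T	50	0.1	DNMT3A	TRUE	FALSE
VS1	1	21000	C	T	50	0.1	TET2	TRUE	FALSE
VS1	1	22000	C	T	50	0.1	ASXL1	TRUE	FALSE
VS1	1	23000	C	T	50	0.1	JAK2	TRUE	FALSE
VS1	1	24000	C	T	50	0.1	TTN	TRUE	TRUE
VS1	1	25000	C	T	50	0.1	SF3B1	TRUE	FALSE
VS1	1	26000	C	T	25	0.35		TRUE	TRUE
VS1	1	27000	C	T	24	0.36		TRUE	FALSE
VS1	1	28000	C	T	0	0		TRUE	FALSE
VS1	1	29000	C	G	24	0.1		FALSE	FALSE
VS1	1	30000	A	G	30	0.2		TRUE	TRUE
VS1	1	31000	G	T	50	0.1	JAK2	FALSE	FALSE
VS1	1	32000	T	C	101	0.1		TRUE	FALSE
VS1	1	33000	G	A	99	0.34		TRUE	TRUE
VS1	1	34000	A	T	60	0.4		FALSE	FALSE
VS1	1	35000	T	C	26	0.01		TRUE	TRUE
VS1	1	36000	C	A	80	0.3	TP53	FALSE	FALSE
VS1	1	37000	G	A	25	0.35	TTN	TRUE	TRUE
VS1	1	38000	A	G	100	0.35		TRUE	TRUE
VS1	1	39000	C	T	38	0.18		TRUE	TRUE
VS1	1	40000	T	G	38	0.18		FALSE	TRUE
VS1	1	41000	T	C	45	0.22		TRUE	TRUE
VS1	1	42000	G	A	52	0.08		TRUE	TRUE
VS1	1	43000	C	T	31	0.29		TRUE	TRUE
VS1	1	44000	A	G	72	0.12		TRUE	TRUE
VS1	1	45000	C	G	41	0.15		FALSE	TRUE
VS1	1	46000	G	C	33	0.09		FALSE	TRUE
VS1	1	47000	C	T	110	0.1		TRUE	FALSE
VS1	1	48000	T	C	20	0.2		TRUE	FALSE
VS1	1	49000	C	T	55	0.45		TRUE	FALSE
VS1	1	50000	G	A	64	0.5		TRUE	FALSE
VS1	1	51000	A	G	47	0.11	PPM1D	TRUE	FALSE
VS1	1	52000	C	T	58	0.07	SRSF2	TRUE	FALSE
VS1	1	53000	T	A	29	0.31		FALSE	TRUE
VS1	1	54000	G	T	97	0.05		FALSE	TRUE
VS1	1	55000	A	C	36	0.26		FALSE	TRUE
VS1	1	56000	C	A	44	0.33		FALSE	TRUE
VS1	1	57000	T	C	88	0.35		TRUE	TRUE
VS1	1	58000	C	T	25	0		TRUE	TRUE
VS1	1	59000	G	A	100	0.36		TRUE	FALSE
VS1	1	60000	A	G	24	0.35		TRUE	FALSE
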