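library	short_name	cdnas	contigs	singletons	tus	pct_r_published
Original standard	OS	12136	3274	1165	4439	67.31
Silica plus	SP	7508	3077	384	3461	57.21
Silica minus	SM	6968	2838	459	3297	54.63
Oval morphotype	OM	4544	2202	214	2416	48.78
Nitrate replete	NR	3632	2028	242	2270	39.01
Nitrate starved	NS	9122	3271	512	3783	60.79
Ammonium adapted	AA	9031	3329	567	3896	60.20
Urea adapted	UA	8552	3157	464	3621	59.82
Tropical accession	TA	4821	2015	160	2175	56.95
Low decadienal	LD	9227	3322	537	3859	61.65
High decadienal	HD	3541	1734	323	2057	44.95
Iron limited	FL	8264	3064	487	3551	59.19
Triradiate morphotype	TM	12566	3055	520	3575	70.49
Blue light	BL	12045	4253	607	4860	59.61
CO2 high 4 days	C4	10283	3564	160	3724	63.78
CO2 high 1 day	C1	10307	3598	165	3763	63.49
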