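gene	snp	chrom	bp	consequence	sift_call	polyphen_call	ref_freq	ref_minor	ref_total	case_freq	case_minor	case_total	p_printed	test
SP110	rs181058279	2	231033860	missense	damaging	possibly_damaging	0.00006	4	66714	0.0019	5	2624	5.45E-06	fisher_exact
AGBL2	rs76215382	11	47711820	missense	damaging	probably_damaging	0.0148	986	66668	0.0247	65	2622	8.48E-05	chi_square
SUCLA2	rs121908538	13	48528645	missense	damaging	probably_damaging	0.00003	2	66524	0.0034	9	2621	3.14E-12	fisher_exact
APH1B	rs745918508	15	63594615	frameshift	LOF	LOF	0.00007	5	66712	0.0088	23	2620	5.40E-29	fisher_exact
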