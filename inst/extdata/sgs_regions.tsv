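families	chrom	band	start_bp	end_bp	length_bp	n_sharing	p_value
709,8556	1	1p34.2	40433771	40555321	121550	6,5	3.47E-12
791533,540775	1	1q31.1-q31.2	190694813	191590362	895549	3,7	4.63E-09
601627	2	2p16.3	50902522	51820543	918021	6	1.94E-10
176860,11593	2	2q32.2-q32.3	191029604	192020729	991125	5,6	4.31E-12
601627	2	2q36.3-q37.1	230899765	231454354	554589	6	2.39E-10
553615	3	3p14.1	64735531	65289530	553999	8	8.87E-11
129334,11593	3	3q26.33	181074751	181229833	155082	4,5	7.94E-12
603481	4	4q26	117379825	118257841	878016	7	3.08E-08
807334	4	4q28.3	131561136	132902055	1340919	5	2.02E-07
8556,66494	4	4q35.1-q35.2	187072383	187513585	441202	4,5	1.82E-12
553615	5	5q23.3-q31.1	129199151	131819921	2620770	9	2.39E-10
553615,603481,176860	5	5q23.3-q31.1	129684909	131819921	2135012	7,7,7	1.30E-18
601627	5	5q33.3-q34	159633484	160328128	694644	7	5.47E-10
553615	6	6q11.1-q12	62563817	64139997	1576180	8	1.34E-10
60205	6	6q24.3	148162328	148621930	459602	5	4.02E-07
601627	7	7p21.2	14144663	15001308	856645	6	2.04E-10
957634,595955	7	7q36.1	150239676	151123529	883853	3,4	6.44E-11
587072,595955	8	8p23.1	9157884	10032894	875010	4,5	4.71E-11
233769	10	10p15.3	2408852	2881331	472479	7	1.11E-09
11593,8556	10	10p12.33	17391660	17576227	184567	4,5	3.11E-12
27251,233769	10	10q21.3	67735584	68057063	321479	7,5	8.22E-15
209487	11	11p11.2-q12.1	47312689	56518769	9206070	6	6.60E-08
540775	11	11q13.3	69482091	69933696	451605	7	6.20E-09
209487,66494	12	12q12	41899312	42298882	399570	5,5	2.14E-12
709	13	13q12.3	29886987	30492217	605320	7	1.86E-08
27251,41469	13	13q14.2	48526833	49283795	756962	5,4	2.93E-12
590241,601627	14	14q23.1-q23.2	60699751	62360464	1660713	5,8	5.91E-14
709	15	15q21.3-q22.2	58601804	59646991	1045187	6	2.74E-08
66494	15	15q22.2	62914165	63686327	772162	6	5.44E-08
27251,233769	18	18q11.2	24414687	24494344	79657	8,6	5.22E-15
27251,622459	19	19q13.12	35836530	36136449	299919	8,3	2.89E-12
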